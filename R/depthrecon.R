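# Feature-based depth reconstruction from stereo EDF pairs:
# preprocessing (frequency-domain low-pass, then Richardson-Lucy
# deconvolution), circular-Hough feature detection, correspondence by
# minimising  cost = dE + dy - S  (normalised energy difference, normalised
# vertical offset, circle metric), disparity-to-depth triangulation, depth
# recovery from a conventional z-stack, and accuracy statistics.

#' Preprocess a view image
#'
#' A circular raised-cosine low-pass filter in the spatial-frequency domain
#' followed by `rl_iterations` Richardson-Lucy multiplicative updates with
#' the given PSF kernel.  A cutoff at or beyond 0.5 cycles/px disables the
#' low-pass (identity); `rl_iterations = 0` skips deconvolution.
#' Nonnegativity is preserved.
#'
#' @param image Nonnegative matrix.
#' @param lowpass_cutoff Radial cutoff in cycles/pixel, in (0, 0.5].
#' @param psf_kernel 2D kernel for deconvolution (normalised internally;
#'   default [bessel_psf_kernel()] at the default pixel size).
#' @param rl_iterations Number of Richardson-Lucy iterations (>= 0).
#' @param rolloff Width of the raised-cosine edge, cycles/pixel.
#' @return Preprocessed matrix, same shape.
#' @export
preprocess <- function(image, lowpass_cutoff = 0.25, psf_kernel = NULL,
                       rl_iterations = 10, rolloff = 0.05) {
  stopifnot(rl_iterations >= 0, lowpass_cutoff > 0)
  out <- image
  if (lowpass_cutoff < 0.5) {
    fr <- sqrt(outer(fft_freq(nrow(image))^2, fft_freq(ncol(image))^2, `+`))
    c1 <- lowpass_cutoff - rolloff / 2
    c2 <- lowpass_cutoff + rolloff / 2
    h <- ifelse(fr <= c1, 1,
                ifelse(fr >= c2, 0, 0.5 * (1 + cos(pi * (fr - c1) / (c2 - c1)))))
    out <- pmax(Re(stats::fft(stats::fft(out) * h, inverse = TRUE)) /
                  length(out), 0)
  }
  if (rl_iterations > 0) {
    psf_kernel <- psf_kernel %||% bessel_psf_kernel(130 / 512)
    s <- sum(psf_kernel)
    if (!is.finite(s) || s <= 0) stop("psf_kernel is not normalisable")
    k <- psf_kernel / s
    kf <- k[nrow(k):1, ncol(k):1, drop = FALSE]  # mirrored kernel
    est <- out
    eps <- 1e-12
    for (i in seq_len(rl_iterations)) {
      denom <- conv2_fft(est, k)
      ratio <- out / pmax(denom, eps)
      est <- est * conv2_fft(ratio, kf)
      est <- pmax(est, 0)
    }
    out <- est
  }
  out
}

#' Detect circular objects with a circular Hough transform
#'
#' Gradient-based voting: edge pixels (gradient magnitude above a threshold)
#' vote at distance r along the inward gradient direction for every radius
#' in the range, and local accumulator maxima become candidate circles.
#' Each candidate is then scored by its perimeter coverage: the fraction of
#' perimeter directions at which an edge pixel with an inward-pointing
#' gradient is found.  This coverage is the circle metric `S` in [0, 1];
#' unlike the raw accumulator count it cannot saturate, and candidates
#' spawned along extended edges (which cover only a short arc) score low.
#' Candidates above `sensitivity` undergo non-maximum suppression across
#' radii and positions, then centres are refined to sub-pixel precision by
#' a background-subtracted intensity centroid restricted to pixels nearer
#' this detection than any other (limits bias from overlapping objects).
#' `energy_E` is the sum of image values inside the fitted circle.
#'
#' @param image Preprocessed nonnegative matrix.
#' @param r_min,r_max Radius search range in pixels.
#' @param sensitivity Detection threshold on `S` (0-1).
#' @param r_step Radius step in pixels.
#' @param edge_threshold Gradient-magnitude threshold as a fraction of the
#'   maximum gradient.
#' @param min_distance Minimum distance between detections in pixels
#'   (default `r_min`).
#' @return Data frame of class `circle_features`: `id`, `x` (column), `y`
#'   (row), `r`, `metric_S`, `energy_E`; attribute `img_dim`.
#' @export
detect_circles <- function(image, r_min = 1.5, r_max = 15, sensitivity = 0.5,
                           r_step = 0.5, edge_threshold = 0.05,
                           min_distance = NULL) {
  if (r_min > r_max) stop("empty radius range (r_min > r_max)")
  min_distance <- min_distance %||% max(r_min, 2)
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      r = numeric(), metric_S = numeric(),
                      energy_E = numeric())
  class(empty) <- c("circle_features", "data.frame")
  attr(empty, "img_dim") <- dim(image)
  if (max(image) <= 0) return(empty)

  sm <- conv2_fft(image, gaussian_kernel2(1))
  n <- nrow(sm); m <- ncol(sm)
  gy <- matrix(0, n, m); gx <- matrix(0, n, m)
  gy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
  gx[, 2:(m - 1)] <- (sm[, 3:m] - sm[, 1:(m - 2)]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  thr <- edge_threshold * max(gmag)
  edge <- which(gmag > thr)
  if (length(edge) == 0) return(empty)
  ei <- (edge - 1) %% n + 1         # row
  ej <- (edge - 1) %/% n + 1        # col
  ux <- gx[edge] / gmag[edge]
  uy <- gy[edge] / gmag[edge]
  uxm <- gx / pmax(gmag, 1e-12)     # full-field unit gradient (for coverage)
  uym <- gy / pmax(gmag, 1e-12)

  radii <- seq(r_min, r_max, by = r_step)
  cand <- list()
  for (r in radii) {
    # bright-on-dark: gradient points toward the interior
    ci <- round(ei + r * uy)
    cj <- round(ej + r * ux)
    ok <- ci >= 1 & ci <= n & cj >= 1 & cj <= m
    acc <- matrix(0, n, m)
    if (any(ok)) {
      idx <- (cj[ok] - 1) * n + ci[ok]
      tab <- tabulate(idx, nbins = n * m)
      acc[] <- tab
    }
    # 3x3 vote pooling; a loose count threshold yields candidates only,
    # the real metric is the perimeter coverage computed below
    score <- box3_sum(acc) / (2 * pi * r)
    pk <- which(score >= 0.2 & score >= local_max3(score))
    if (length(pk) > 0) {
      cand[[length(cand) + 1]] <- data.frame(
        y = (pk - 1) %% n + 1, x = (pk - 1) %/% n + 1, r = r)
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  cand$S <- perimeter_coverage(cand, gmag > thr, uxm, uym)
  cand <- cand[cand$S >= sensitivity, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # non-maximum suppression across radii/positions.  Ranking by total
  # perimeter evidence r*S (not S alone) makes the object-scale circle win
  # over small concentric deconvolution-ring artifacts with saturated
  # coverage; suppression reaches r+4 px to absorb satellite candidates
  # spawned around a large circle evaluated at the wrong radius.
  cand <- cand[order(-(cand$r * cand$S), cand$r), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x[j] - cand$x[i])^2 + (cand$y[j] - cand$y[i])^2
      keep[j][d2 < pmax(min_distance, cand$r[i] + 4)^2] <- FALSE
    }
  }
  det <- cand[keep, , drop = FALSE]

  # sub-pixel centre refinement: background-subtracted intensity centroid
  # over the disc, restricted to pixels whose nearest detection is this one
  refine <- refine_centres(image, det)
  # radius refinement: the coverage test tolerates the full width of the
  # edge band, so the winning candidate radius can overshoot; relocate it
  # to the gradient-magnitude ridge around the refined centre
  rfine <- vapply(seq_len(nrow(refine)), function(k) {
    refine_radius(gmag, refine$x[k], refine$y[k], det$r[k], r_min, r_max)
  }, numeric(1))
  energy <- vapply(seq_len(nrow(refine)), function(k) {
    circle_sum(image, refine$x[k], refine$y[k], rfine[k])
  }, numeric(1))
  out <- data.frame(id = seq_len(nrow(det)), x = refine$x, y = refine$y,
                    r = rfine, metric_S = det$S, energy_E = energy)
  class(out) <- c("circle_features", "data.frame")
  attr(out, "img_dim") <- dim(image)
  out
}

# Fraction of perimeter directions of each candidate circle at which an
# edge pixel with an inward-pointing gradient exists (checked at radius
# r and r +/- 0.5 to absorb discretisation).  Dot-product gate 0.5 accepts
# gradients within 60 degrees of the exact inward direction.
perimeter_coverage <- function(cand, edge_mask, uxm, uym, n_angles = 32L) {
  n <- nrow(edge_mask); m <- ncol(edge_mask)
  phi <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  cs <- cos(phi); sn <- sin(phi)
  vapply(seq_len(nrow(cand)), function(k) {
    covered <- logical(n_angles)
    for (dr in c(-0.5, 0, 0.5)) {
      r <- cand$r[k] + dr
      if (r <= 0) next
      px <- round(cand$x[k] + r * cs)
      py <- round(cand$y[k] + r * sn)
      ok <- px >= 1 & px <= m & py >= 1 & py <= n & !covered
      if (!any(ok)) next
      idx <- (px[ok] - 1) * n + py[ok]
      inward <- -(uxm[idx] * cs[ok] + uym[idx] * sn[ok])
      covered[ok] <- edge_mask[idx] & inward > 0.5
    }
    mean(covered)
  }, numeric(1))
}

box3_sum <- function(a) {
  n <- nrow(a); m <- ncol(a)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- a
  out <- matrix(0, n, m)
  for (di in 0:2) for (dj in 0:2) {
    out <- out + p[(1 + di):(n + di), (1 + dj):(m + dj)]
  }
  out
}

local_max3 <- function(a) {
  n <- nrow(a); m <- ncol(a)
  p <- matrix(-Inf, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- a
  mx <- matrix(-Inf, n, m)
  for (di in 0:2) for (dj in 0:2) {
    mx <- pmax(mx, p[(1 + di):(n + di), (1 + dj):(m + dj)])
  }
  mx
}

# Mean gradient magnitude on the circle perimeter as a function of radius,
# maximised over a fine grid around the candidate radius (+/- 4 px).
refine_radius <- function(gmag, x, y, r0, r_min, r_max, n_angles = 48L) {
  n <- nrow(gmag); m <- ncol(gmag)
  phi <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  cs <- cos(phi); sn <- sin(phi)
  radii <- seq(max(r_min, r0 - 4), min(r_max, r0 + 4), by = 0.25)
  ridge <- vapply(radii, function(r) {
    px <- round(x + r * cs); py <- round(y + r * sn)
    ok <- px >= 1 & px <= m & py >= 1 & py <= n
    if (!any(ok)) return(0)
    mean(gmag[(px[ok] - 1) * n + py[ok]])
  }, numeric(1))
  radii[which.max(ridge)]
}

circle_sum <- function(image, x, y, r) {
  n <- nrow(image); m <- ncol(image)
  ir <- max(1L, floor(y - r)):min(n, ceiling(y + r))
  jr <- max(1L, floor(x - r)):min(m, ceiling(x + r))
  d2 <- outer((ir - y)^2, (jr - x)^2, `+`)
  sum(image[ir, jr][d2 <= r^2])
}

refine_centres <- function(image, det) {
  n <- nrow(image); m <- ncol(image)
  xs <- det$x; ys <- det$y
  for (k in seq_len(nrow(det))) {
    r <- det$r[k] + 1.5
    ir <- max(1L, floor(ys[k] - r)):min(n, ceiling(ys[k] + r))
    jr <- max(1L, floor(xs[k] - r)):min(m, ceiling(xs[k] + r))
    sub <- image[ir, jr, drop = FALSE]
    d2 <- outer((ir - ys[k])^2, (jr - xs[k])^2, `+`)
    inside <- d2 <= r^2
    # assign pixels to the nearest detection to limit overlap bias
    if (nrow(det) > 1) {
      others <- setdiff(which(
        (det$x - det$x[k])^2 + (det$y - det$y[k])^2 <
          (det$r + det$r[k] + 4)^2), k)
      for (o in others) {
        d2o <- outer((ir - det$y[o])^2, (jr - det$x[o])^2, `+`)
        inside <- inside & (d2 <= d2o)
      }
    }
    if (!any(inside)) next
    ring <- d2 > r^2 & d2 <= (r + 2)^2
    bg <- if (any(ring)) stats::median(sub[ring]) else 0
    w <- pmax(sub - bg, 0) * inside
    sw <- sum(w)
    if (sw > 0) {
      ys[k] <- sum(w * matrix(ir, length(ir), length(jr))) / sw
      xs[k] <- sum(w * matrix(jr, length(ir), length(jr), byrow = TRUE)) / sw
    }
  }
  data.frame(x = xs, y = ys)
}

#' Match circle features across a stereo pair
#'
#' For each left feature the admissible right candidates satisfy
#' `|y_L - y_R| <= epipolar_window_px` and `|x_L - x_R| <= max_disparity_px`.
#' The match cost is `dE + dy - S` where
#' `dE = |E_L - E_R| / max(E_L, E_R)` (normalised energy difference),
#' `dy = |y_L - y_R| / epipolar_window_px` (normalised vertical offset) and
#' `S` is the right candidate's circle metric; all three terms are in
#' [0, 1].  One-to-one matching is enforced greedily in ascending cost
#' (`method = "greedy"`, default) or by exact minimisation of the total cost
#' over all admissible one-to-one assignments (`method = "global"`,
#' exhaustive with pruning — small candidate sets only).
#'
#' @param left,right `circle_features` from the two views (same image
#'   shape).
#' @param max_disparity_px Disparity gate in pixels.
#' @param epipolar_window_px Vertical gate in pixels.
#' @param method `"greedy"` or `"global"`.
#' @return Data frame of class `correspondences`: `left_id`, `right_id`,
#'   `cost_delta`, `delta_E`, `delta_y`, `disparity_px` (x_left - x_right);
#'   attribute `unmatched_left` holds ids of left features without a match.
#' @export
match_features <- function(left, right, max_disparity_px = 10,
                           epipolar_window_px = 3,
                           method = c("greedy", "global")) {
  method <- match.arg(method)
  empty <- data.frame(left_id = integer(), right_id = integer(),
                      cost_delta = numeric(), delta_E = numeric(),
                      delta_y = numeric(), disparity_px = numeric())
  class(empty) <- c("correspondences", "data.frame")
  if (nrow(left) == 0 || nrow(right) == 0) {
    attr(empty, "unmatched_left") <- left$id
    return(empty)
  }
  pairs <- expand.grid(il = seq_len(nrow(left)), ir = seq_len(nrow(right)))
  dyr <- abs(left$y[pairs$il] - right$y[pairs$ir])
  dxr <- left$x[pairs$il] - right$x[pairs$ir]
  adm <- dyr <= epipolar_window_px & abs(dxr) <= max_disparity_px
  pairs <- pairs[adm, , drop = FALSE]
  if (nrow(pairs) == 0) {
    attr(empty, "unmatched_left") <- left$id
    return(empty)
  }
  el <- left$energy_E[pairs$il]; er <- right$energy_E[pairs$ir]
  de <- abs(el - er) / pmax(pmax(el, er), 1e-12)
  dy <- abs(left$y[pairs$il] - right$y[pairs$ir]) / epipolar_window_px
  cost <- de + dy - right$metric_S[pairs$ir]
  tab <- data.frame(il = pairs$il, ir = pairs$ir, cost = cost,
                    de = de, dy = dy,
                    disp = left$x[pairs$il] - right$x[pairs$ir])

  sel <- if (method == "greedy") greedy_assign(tab, nrow(left), nrow(right))
         else global_assign(tab, nrow(left), nrow(right))
  out <- data.frame(left_id = left$id[sel$il], right_id = right$id[sel$ir],
                    cost_delta = sel$cost, delta_E = sel$de,
                    delta_y = sel$dy, disparity_px = sel$disp)
  class(out) <- c("correspondences", "data.frame")
  attr(out, "unmatched_left") <- setdiff(left$id, out$left_id)
  out
}

greedy_assign <- function(tab, nl, nr) {
  tab <- tab[order(tab$cost), , drop = FALSE]
  usedl <- logical(nl); usedr <- logical(nr)
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!usedl[tab$il[i]] && !usedr[tab$ir[i]]) {
      keep[i] <- TRUE
      usedl[tab$il[i]] <- TRUE
      usedr[tab$ir[i]] <- TRUE
    }
  }
  tab[keep, , drop = FALSE]
}

# Exact minimum-total-cost one-to-one assignment over the admissible pairs,
# maximising cardinality first.  Depth-first search with branch-and-bound;
# intended for the small candidate sets of sparse-bead images.
global_assign <- function(tab, nl, nr) {
  lefts <- sort(unique(tab$il))
  by_left <- split(seq_len(nrow(tab)), tab$il)
  best <- list(cost = Inf, nmatch = -1L, rows = integer())
  lb_left <- vapply(by_left, function(rows) min(tab$cost[rows]), numeric(1))
  recurse <- function(k, used_r, rows, cost) {
    if (k > length(lefts)) {
      nm <- length(rows)
      if (nm > best$nmatch || (nm == best$nmatch && cost < best$cost)) {
        best <<- list(cost = cost, nmatch = nm, rows = rows)
      }
      return()
    }
    # bound: remaining lefts can add at most their own minimum costs
    rem <- if (k <= length(lefts)) sum(pmin(lb_left[k:length(lefts)], 0)) else 0
    max_nmatch <- length(rows) + (length(lefts) - k + 1)
    if (max_nmatch < best$nmatch ||
        (max_nmatch == best$nmatch && cost + rem >= best$cost)) {
      return()
    }
    cand_rows <- by_left[[as.character(lefts[k])]]
    cand_rows <- cand_rows[order(tab$cost[cand_rows])]
    for (rw in cand_rows) {
      if (tab$ir[rw] %in% used_r) next
      recurse(k + 1, c(used_r, tab$ir[rw]), c(rows, rw), cost + tab$cost[rw])
    }
    recurse(k + 1, used_r, rows, cost)    # leave this left unmatched
  }
  recurse(1L, integer(), integer(), 0)
  tab[best$rows, , drop = FALSE]
}

#' Triangulate matched features to object depths
#'
#' Depth from disparity via [depth_from_disparity_geometry()]; lateral
#' position from the left-view circle centre, converted to um relative to
#' the image centre.
#'
#' @param matches A [match_features()] result.
#' @param left The left-view `circle_features` (for positions).
#' @param geom A [stereo_geometry()].
#' @return Data frame of class `object_depths`: `id` (left feature id),
#'   `x`, `y`, `z` (um), `disparity_px`, `matched`.  Unmatched left features
#'   appear with `matched = FALSE` and `z = NA`.
#' @export
triangulate <- function(matches, left, geom) {
  dims <- attr(left, "img_dim") %||% c(max(left$y) + 1, max(left$x) + 1)
  ctr <- (dims + 1) / 2  # (row, col)
  p <- geom$pixel_size
  z <- depth_from_disparity_geometry(matches$disparity_px, geom)
  idx <- match(matches$left_id, left$id)
  out <- data.frame(id = matches$left_id,
                    x = (left$x[idx] - ctr[2]) * p,
                    y = (left$y[idx] - ctr[1]) * p,
                    z = z,
                    disparity_px = matches$disparity_px,
                    matched = rep(TRUE, nrow(matches)))
  un <- attr(matches, "unmatched_left")
  if (length(un) > 0) {
    idx <- match(un, left$id)
    out <- rbind(out, data.frame(id = un,
                                 x = (left$x[idx] - ctr[2]) * p,
                                 y = (left$y[idx] - ctr[1]) * p,
                                 z = NA_real_, disparity_px = NA_real_,
                                 matched = rep(FALSE, length(un))))
  }
  out <- out[order(out$id), ]
  rownames(out) <- NULL
  class(out) <- c("object_depths", "data.frame")
  out
}

#' Object depths from a conventional z-stack
#'
#' Ground-truth style depth recovery: for each circle feature, the mean
#' intensity inside the circle is evaluated on every plane and the depth is
#' the z of the maximising plane (ties broken toward lower z); optional
#' parabolic refinement interpolates between the neighbouring planes.
#'
#' @param stack A `z_stack` (see [render_zstack()]), or a list with `values`
#'   (3D array) and `z` (plane positions).
#' @param features A `circle_features` data frame.
#' @param refine Parabolic sub-plane refinement (default TRUE).
#' @return Data frame: `id`, `z`, `in_bounds`.  Features outside the stack's
#'   lateral bounds are flagged `in_bounds = FALSE` with `z = NA`.
#' @export
depths_from_stack <- function(stack, features, refine = TRUE) {
  vol <- stack$values
  zax <- stack$z
  n <- dim(vol)[1]; m <- dim(vol)[2]
  res <- data.frame(id = features$id, z = NA_real_,
                    in_bounds = TRUE)
  for (k in seq_len(nrow(features))) {
    x <- features$x[k]; y <- features$y[k]; r <- features$r[k]
    if (x < 1 || x > m || y < 1 || y > n) {
      res$in_bounds[k] <- FALSE
      next
    }
    prof <- vapply(seq_along(zax), function(iz) {
      circle_sum(vol[, , iz], x, y, r)
    }, numeric(1))
    imax <- which.max(prof)     # which.max returns the first (lowest z) tie
    zk <- zax[imax]
    if (refine && imax > 1 && imax < length(zax)) {
      a <- prof[imax - 1]; b <- prof[imax]; cc <- prof[imax + 1]
      den <- a - 2 * b + cc
      if (den < 0) {
        zk <- zk + 0.5 * (a - cc) / den * (zax[2] - zax[1])
      }
    }
    res$z[k] <- zk
  }
  res
}

#' Depth-error statistics against ground truth
#'
#' Joins recovered and true depths by object id, reports the fraction of
#' matched objects with absolute depth error below each threshold, and fits
#' a Gaussian density to the signed-error histogram by least squares to
#' estimate the error spread `sigma`.
#'
#' @param recovered An `object_depths` data frame (or any frame with `id`,
#'   `z`, optionally `matched`).
#' @param truth Data frame with `id` and `z` (um).
#' @param thresholds Error thresholds in um (default `c(2, 5)`).
#' @param bin_width Histogram bin width in um for the sigma fit.
#' @return List of class `depth_error_stats`: `n_objects`, `n_matched`,
#'   `errors` (absolute, per matched object), `signed_errors`,
#'   `fraction_within` (named by threshold), `rmse`, `sigma_fit`,
#'   `sigma_se` (NA when fewer than 3 matched objects or the fit fails).
#' @export
evaluate_depths <- function(recovered, truth, thresholds = c(2, 5),
                            bin_width = 1) {
  if (!any(recovered$id %in% truth$id)) {
    stop("recovered and truth share no object ids")
  }
  idx <- match(recovered$id, truth$id)
  ok <- !is.na(idx)
  rec <- recovered[ok, , drop = FALSE]
  tz <- truth$z[idx[ok]]
  matched <- if ("matched" %in% names(rec)) rec$matched & !is.na(rec$z)
             else !is.na(rec$z)
  signed <- rec$z[matched] - tz[matched]
  errs <- abs(signed)
  fr <- vapply(thresholds, function(t) mean(errs <= t), numeric(1))
  names(fr) <- as.character(thresholds)
  sigma <- sigma_se <- NA_real_
  if (length(signed) >= 3) {
    fit <- fit_gaussian_sigma(signed, bin_width)
    sigma <- fit$sigma; sigma_se <- fit$se
  }
  structure(list(n_objects = nrow(rec), n_matched = sum(matched),
                 errors = errs, signed_errors = signed,
                 fraction_within = fr,
                 rmse = if (length(signed)) sqrt(mean(signed^2)) else NA_real_,
                 sigma_fit = sigma, sigma_se = sigma_se),
            class = "depth_error_stats")
}

# Least-squares fit of A*exp(-(x-mu)^2/(2 s^2)) to the histogram of signed
# errors; falls back to the sample standard deviation if nls fails.
fit_gaussian_sigma <- function(signed, bin_width = 1) {
  rng <- range(signed)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width - bin_width / 2,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(signed, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  s0 <- max(stats::sd(signed), bin_width / 2)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                 start = list(A = max(df$y), mu = mean(signed), s = s0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(sigma = stats::sd(signed), se = NA_real_))
  }
  # summary() can fail on a perfect (zero-residual) fit; the estimate is
  # still valid, only its standard error is then unavailable
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) {
    return(list(sigma = abs(stats::coef(fit)[["s"]]), se = NA_real_))
  }
  list(sigma = abs(co["s", "Estimate"]), se = co["s", "Std. Error"])
}

#' Full stereo-pair depth reconstruction
#'
#' Convenience pipeline: preprocess both views, detect circles (with the
#' looser right-view threshold), match, triangulate.
#'
#' @param pair A `stereo_pair`.
#' @param geom A [stereo_geometry()] (defaulted from the pair).
#' @param psf_kernel Deconvolution kernel (default [bessel_psf_kernel()] at
#'   the pair's pixel size).
#' @param lowpass_cutoff,rl_iterations Preprocessing controls.
#' @param r_min,r_max,sensitivity Detection controls (left view); the right
#'   view uses `right_sensitivity_factor * sensitivity`.
#' @param right_sensitivity_factor Looser right-view threshold factor
#'   (default 0.8).
#' @param max_disparity_px,epipolar_window_px Matching gates.
#' @return List: `depths` (`object_depths`), `left_features`,
#'   `right_features`, `matches`, `pre_left`, `pre_right`.
#' @export
reconstruct_depths <- function(pair, geom = NULL, psf_kernel = NULL,
                               lowpass_cutoff = 0.25, rl_iterations = 10,
                               r_min = 1.5, r_max = 15, sensitivity = 0.5,
                               right_sensitivity_factor = 0.8,
                               max_disparity_px = 10,
                               epipolar_window_px = 3) {
  geom <- geom %||% stereo_geometry(parallax_alpha = pair$parallax_alpha,
                                    pixel_size = pair$pixel_size)
  psf_kernel <- psf_kernel %||% bessel_psf_kernel(geom$pixel_size)
  pl <- preprocess(pair$left, lowpass_cutoff, psf_kernel, rl_iterations)
  pr <- preprocess(pair$right, lowpass_cutoff, psf_kernel, rl_iterations)
  fl <- detect_circles(pl, r_min, r_max, sensitivity)
  fr <- detect_circles(pr, r_min, r_max,
                       sensitivity * right_sensitivity_factor)
  mt <- match_features(fl, fr, max_disparity_px, epipolar_window_px)
  dp <- triangulate(mt, fl, geom)
  list(depths = dp, left_features = fl, right_features = fr, matches = mt,
       pre_left = pl, pre_right = pr)
}
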