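# Synthetic-data engine: random bead phantoms with known 3D positions, the
# tilted extended-depth-of-field (EDF) forward imaging model producing
# interlaced raw frames, Poisson noise, and conventional z-stack rendering
# for ground truth.
#
# Display-space image convention: a rendered view is an n_fast x m_slow
# matrix; columns index the slow scan axis x (the disparity axis, horizontal
# after the 90-degree rotation of the raw frame), rows index the fast axis y.
# Physical coordinates are centred: column j maps to
# x = (j - (M+1)/2) * pixel_size, row i to y = (i - (N+1)/2) * pixel_size,
# and z = 0 is the zero-disparity reference plane.

#' Random 3D bead phantom
#'
#' Beads emulate a slide of mixed fluorescent microspheres (1 um and 6 um
#' diameter by default).  Positions are uniform over the centred extent
#' subject to a minimum pairwise lateral (xy) separation; separation is
#' enforced laterally because the EDF projection collapses z, so only
#' lateral overlap degrades the images.  Brightness is per unit path length,
#' equal dye density for all beads by default.
#'
#' @param n_beads Number of beads.
#' @param extent Lengths `c(x, y, z)` in um of the phantom volume
#'   (default 130 x 130 x 90).
#' @param radii Candidate bead radii in um (default `c(0.5, 3.0)`).
#' @param radii_prob Sampling probabilities for `radii` (default equal).
#' @param min_separation Minimum pairwise lateral separation in um.
#' @param edge_margin Extra keep-out from the lateral faces in um, added to
#'   each bead's radius.
#' @param brightness Per-bead brightness (recycled).
#' @param seed Integer seed; the phantom is reproducible for a fixed seed.
#' @param max_tries Rejection-sampling budget per bead.
#' @return Object of class `bead_phantom`: data frame `beads`
#'   (id, x, y, z, radius, brightness), `extent`, `seed`.
#' @export
make_phantom <- function(n_beads, extent = c(130, 130, 90),
                         radii = c(0.5, 3.0), radii_prob = NULL,
                         min_separation = 5, edge_margin = 2,
                         brightness = 1, seed = 1, max_tries = 2000L) {
  stopifnot(n_beads >= 0, all(extent > 0), min_separation >= 0)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  if (n_beads == 0) {
    beads <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        z = numeric(), radius = numeric(),
                        brightness = numeric())
    return(structure(list(beads = beads, extent = extent, seed = seed),
                     class = "bead_phantom"))
  }
  radii_prob <- radii_prob %||% rep(1 / length(radii), length(radii))
  r <- sample(radii, n_beads, replace = TRUE, prob = radii_prob)
  brightness <- rep_len(brightness, n_beads)
  xs <- ys <- zs <- numeric(n_beads)
  for (i in seq_len(n_beads)) {
    placed <- FALSE
    hw <- extent / 2
    for (k in seq_len(max_tries)) {
      m <- r[i] + edge_margin
      if (2 * m >= extent[1] || 2 * m >= extent[2]) {
        stop("bead radius + edge_margin exceeds the lateral extent")
      }
      x <- stats::runif(1, -hw[1] + m, hw[1] - m)
      y <- stats::runif(1, -hw[2] + m, hw[2] - m)
      z <- stats::runif(1, -hw[3] + min(r[i], hw[3]), hw[3] - min(r[i], hw[3]))
      if (i == 1 ||
          all(sqrt((xs[seq_len(i - 1)] - x)^2 +
                   (ys[seq_len(i - 1)] - y)^2) >= min_separation)) {
        xs[i] <- x; ys[i] <- y; zs[i] <- z
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place bead ", i, " after ", max_tries,
           " tries; relax min_separation or enlarge the extent")
    }
  }
  beads <- data.frame(id = seq_len(n_beads), x = xs, y = ys, z = zs,
                      radius = r, brightness = brightness)
  structure(list(beads = beads, extent = extent, seed = seed),
            class = "bead_phantom")
}

#' Translate a phantom (for time-series simulations)
#'
#' @param phantom A [make_phantom()] result.
#' @param offset Length-3 displacement `c(dx, dy, dz)` in um.
#' @return The translated phantom.
#' @export
translate_phantom <- function(phantom, offset) {
  phantom$beads$x <- phantom$beads$x + offset[1]
  phantom$beads$y <- phantom$beads$y + offset[2]
  phantom$beads$z <- phantom$beads$z + offset[3]
  phantom
}

#' Lateral two-photon excitation kernel
#'
#' The ideal Bessel-beam two-photon lateral profile `J0(k_r rho)^4`,
#' truncated at the third zero of `J0` and sum-normalised; the default
#' rendering kernel for the EDF forward model.
#'
#' @param pixel_size Pixel pitch in um.
#' @param config An [optical_config()] supplying `annulus_na` and wavelength.
#' @return Square numeric matrix (odd side), sum = 1.
#' @export
bessel_psf_kernel <- function(pixel_size, config = optical_config()) {
  kr <- 2 * pi * config$annulus_na / config$wavelength
  j0_zero3 <- 8.6537279129
  rmax <- j0_zero3 / kr
  hw <- max(1L, ceiling(rmax / pixel_size))
  ax <- seq(-hw, hw) * pixel_size
  rho <- sqrt(outer(ax^2, ax^2, `+`))
  k <- ifelse(rho <= rmax, besselJ(kr * rho, 0)^4, 0)
  k / sum(k)
}

# Chord length through a solid sphere: 2*sqrt(r^2 - rho^2), the projected
# intensity of a uniformly dyed bead per unit brightness.
bead_footprint <- function(dx_px, dy_px, radius_px) {
  rho2 <- outer(dy_px^2, dx_px^2, `+`)
  ifelse(rho2 < radius_px^2, 2 * sqrt(pmax(radius_px^2 - rho2, 0)), 0)
}

#' Render one EDF view of a phantom
#'
#' Shear-projection forward model: each bead's 3D intensity is projected
#' along the view's beam direction, i.e. its lateral position is shifted by
#' `+z*tan(alpha/2)` (left view) or `-z*tan(alpha/2)` (right view), drawn as
#' a projected solid sphere (chord length per pixel, in um of path), then
#' the whole image is convolved with the lateral two-photon kernel.  The
#' Bessel axial envelope is treated as flat across the depth range (its
#' 160 um FWHM exceeds the 90 um range).
#'
#' @param phantom A [make_phantom()] result.
#' @param view `"left"` or `"right"`.
#' @param geom A [stereo_geometry()].
#' @param frame A [frame_geometry()].
#' @param lateral_psf Convolution kernel (default [bessel_psf_kernel()] at
#'   the frame's pixel size).
#' @return `n_fast x m_slow` nonnegative matrix (display space).
#' @export
render_view <- function(phantom, view = c("left", "right"), geom, frame,
                        lateral_psf = NULL) {
  view <- match.arg(view)
  s <- if (view == "left") 1 else -1
  shear <- s * tan(geom$parallax_alpha / 2 * pi / 180)
  img <- render_projection(phantom, frame, shear)
  lateral_psf <- lateral_psf %||% bessel_psf_kernel(frame$pixel_size)
  if (nrow(lateral_psf) > nrow(img) || ncol(lateral_psf) > ncol(img)) {
    stop("lateral_psf kernel is wider than the image")
  }
  pmax(conv2_fft(img, lateral_psf), 0)
}

# Unconvolved shear projection shared by render_view (shear = +/- tan(a/2))
# and the untilted projection (shear = 0).
render_projection <- function(phantom, frame, shear) {
  n <- frame$n_fast; m <- frame$m_slow; p <- frame$pixel_size
  img <- matrix(0, n, m)
  b <- phantom$beads
  if (nrow(b) == 0) return(img)
  for (i in seq_len(nrow(b))) {
    xc <- (b$x[i] + shear * b$z[i]) / p + (m + 1) / 2   # column, px
    yc <- b$y[i] / p + (n + 1) / 2                      # row, px
    rpx <- b$radius[i] / p
    jr <- max(1L, floor(xc - rpx - 1)):min(m, ceiling(xc + rpx + 1))
    ir <- max(1L, floor(yc - rpx - 1)):min(n, ceiling(yc + rpx + 1))
    if (length(jr) == 0 || length(ir) == 0) next
    fp <- bead_footprint(jr - xc, ir - yc, rpx) * p * b$brightness[i]
    img[ir, jr] <- img[ir, jr] + fp
  }
  img
}

#' Poisson shot noise
#'
#' Scales the image so its maximum expects `photons_at_peak` counts and
#' draws independent Poisson counts per pixel.
#'
#' @param image Nonnegative matrix.
#' @param photons_at_peak Expected photon count at the image maximum.
#' @param seed Integer seed (reproducible realisation).
#' @return Matrix of counts (same shape).
#' @export
add_noise <- function(image, photons_at_peak, seed = 1) {
  stopifnot(photons_at_peak > 0)
  mx <- max(image)
  if (mx == 0) return(image)
  set.seed(seed)
  matrix(stats::rpois(length(image), image / mx * photons_at_peak),
         nrow(image), ncol(image))
}

#' Interlace two views into a raw scan frame
#'
#' The inverse of [deinterlace()]: each display-space view is rotated 90
#' degrees clockwise back into scan space (rows = slow-axis lines) and the
#' line rows interleaved L,R,L,R..., yielding the `2M x N` raw frame the
#' scanner would produce (each line position excited twice).
#'
#' @param left,right `n_fast x m_slow` matrices (same shape).
#' @param frame A [frame_geometry()] (shape check).
#' @return Object of class `raw_frame`: `values` (`2*m_slow x n_fast`
#'   matrix), `frame`.
#' @export
interlace_views <- function(left, right, frame) {
  if (!identical(dim(left), dim(right))) stop("left/right shape mismatch")
  if (!identical(dim(left), c(frame$n_fast, frame$m_slow))) {
    stop("views do not match the frame geometry (expected ",
         frame$n_fast, " x ", frame$m_slow, ")")
  }
  ls <- rot90cw(left)
  rs <- rot90cw(right)
  raw <- matrix(0, 2 * frame$m_slow, frame$n_fast)
  raw[seq(1, 2 * frame$m_slow, by = 2), ] <- ls
  raw[seq(2, 2 * frame$m_slow, by = 2), ] <- rs
  structure(list(values = raw, frame = frame), class = "raw_frame")
}

#' Ground-truth table for a phantom
#'
#' Closed-form predicted disparity and left/right image centroids per bead:
#' `disparity_px = 2 * z * tan(alpha/2) / pixel_size`.
#'
#' @param phantom A [make_phantom()] result.
#' @param geom A [stereo_geometry()].
#' @param frame A [frame_geometry()].
#' @return Data frame: id, x, y, z, radius, disparity_px, col_left,
#'   col_right, row (pixel coordinates in display space).
#' @export
ground_truth_table <- function(phantom, geom, frame) {
  b <- phantom$beads
  p <- frame$pixel_size
  th <- tan(geom$parallax_alpha / 2 * pi / 180)
  data.frame(
    id = b$id, x = b$x, y = b$y, z = b$z, radius = b$radius,
    disparity_px = 2 * b$z * th / p,
    col_left = (b$x + th * b$z) / p + (frame$m_slow + 1) / 2,
    col_right = (b$x - th * b$z) / p + (frame$m_slow + 1) / 2,
    row = b$y / p + (frame$n_fast + 1) / 2
  )
}

#' Render a conventional two-photon z-stack
#'
#' Emulates the ground-truth acquisition: untilted plane-by-plane imaging.
#' Each plane receives, per bead, the portion of the bead's chord that falls
#' inside the plane's slab `[z_k - dz/2, z_k + dz/2]`, convolved with the
#' lateral kernel; since the slabs tile the chord, the stack's z sum equals
#' the untilted EDF projection exactly.
#'
#' @param phantom A [make_phantom()] result.
#' @param frame A [frame_geometry()].
#' @param lateral_psf Kernel as in [render_view()].
#' @param z_spacing Plane spacing in um.
#' @param z_range Length-2 range in um (default the phantom's z extent).
#' @return Object of class `z_stack`: array `values` (n_fast x m_slow x K),
#'   `z` plane positions, `frame`.
#' @export
render_zstack <- function(phantom, frame, lateral_psf = NULL,
                          z_spacing = 1, z_range = NULL) {
  stopifnot(z_spacing > 0)
  z_range <- z_range %||% (c(-0.5, 0.5) * phantom$extent[3])
  zk <- seq(z_range[1] + z_spacing / 2, z_range[2], by = z_spacing)
  lateral_psf <- lateral_psf %||% bessel_psf_kernel(frame$pixel_size)
  n <- frame$n_fast; m <- frame$m_slow; p <- frame$pixel_size
  vol <- array(0, c(n, m, length(zk)))
  b <- phantom$beads
  for (k in seq_along(zk)) {
    img <- matrix(0, n, m)
    for (i in seq_len(nrow(b))) {
      if (abs(zk[k] - b$z[i]) > b$radius[i] + z_spacing / 2) next
      xc <- b$x[i] / p + (m + 1) / 2
      yc <- b$y[i] / p + (n + 1) / 2
      rpx <- b$radius[i] / p
      jr <- max(1L, floor(xc - rpx - 1)):min(m, ceiling(xc + rpx + 1))
      ir <- max(1L, floor(yc - rpx - 1)):min(n, ceiling(yc + rpx + 1))
      rho2 <- outer(((ir - yc) * p)^2, ((jr - xc) * p)^2, `+`)
      half_chord <- sqrt(pmax(b$radius[i]^2 - rho2, 0))
      # slab overlap of [z_bead - c, z_bead + c] with [zk - dz/2, zk + dz/2]
      lo <- pmax(b$z[i] - half_chord, zk[k] - z_spacing / 2)
      hi <- pmin(b$z[i] + half_chord, zk[k] + z_spacing / 2)
      img[ir, jr] <- img[ir, jr] + pmax(hi - lo, 0) * b$brightness[i]
    }
    if (any(img > 0)) img <- pmax(conv2_fft(img, lateral_psf), 0)
    vol[, , k] <- img
  }
  structure(list(values = vol, z = zk, frame = frame), class = "z_stack")
}

#' Write phantom and ground truth to disk
#'
#' @param phantom A [make_phantom()] result.
#' @param truth A [ground_truth_table()] result.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_phantom <- function(phantom, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pcsv <- file.path(dir, "phantom.csv")
  tcsv <- file.path(dir, "truth.csv")
  utils::write.csv(phantom$beads, pcsv, row.names = FALSE)
  utils::write.csv(truth, tcsv, row.names = FALSE)
  jsonlite::write_json(list(extent = phantom$extent, seed = phantom$seed),
                       file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(pcsv, tcsv))
}
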