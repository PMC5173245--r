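# Feature-based depth reconstruction: preprocessing, circular Hough
# detection, Eq.-style correspondence, triangulation, stack depths and
# error statistics.

test_that("preprocess: identity settings, RL fixed point, sharpening", {
  img <- matrix(runif(64 * 64), 64)
  out <- preprocess(img, lowpass_cutoff = 0.5, rl_iterations = 0)
  expect_lt(max(abs(out - img)), 1e-6 * max(img))
  u <- matrix(3, 32, 32)
  k <- test_kernel()
  expect_equal(preprocess(u, 0.5, k, rl_iterations = 5), u,
               tolerance = 1e-10)                     # RL fixed point
  pt <- matrix(0, 64, 64); pt[33, 33] <- 1
  blur <- conv2_fft(pt, k)
  sharp <- preprocess(blur, 0.5, k, rl_iterations = 10)
  expect_gt(max(sharp), max(blur))                    # peak restored upward
  expect_true(all(sharp >= 0))
  expect_error(preprocess(img, 0.25, matrix(0, 5, 5), 5), "normalisable")
})

test_that("low-pass filter attenuates high frequencies only", {
  n <- 64
  x <- matrix(rep(seq_len(n), n), n)
  lowf <- sin(2 * pi * (4 / 64) * x)    # integer bins: no spectral leakage
  highf <- sin(2 * pi * (28 / 64) * x)  # 0.4375 cycles/px
  fl <- preprocess(lowf + 2, lowpass_cutoff = 0.25, rl_iterations = 0) - 2
  fh <- preprocess(highf + 2, lowpass_cutoff = 0.25, rl_iterations = 0) - 2
  expect_gt(stats::sd(fl), 0.9 * stats::sd(lowf))
  expect_lt(stats::sd(fh), 0.05 * stats::sd(highf))
})

test_that("detect_circles finds rendered discs with px-level accuracy", {
  k <- test_kernel()
  expect_equal(nrow(detect_circles(matrix(0, 64, 64))), 0)
  expect_error(detect_circles(matrix(1, 16, 16), r_min = 5, r_max = 2),
               "radius")
  n <- 128
  d2 <- outer((1:n - 64.5)^2, (1:n - 64.5)^2, `+`)
  img <- conv2_fft((d2 <= 12^2) * 1.0, k)
  f <- detect_circles(preprocess(img, 0.25, k, 10))
  expect_equal(nrow(f), 1)                            # exactly one
  expect_lt(abs(f$x - 64.5), 1)
  expect_lt(abs(f$y - 64.5), 1)
  expect_lt(abs(f$r - 12), 1)
  expect_true(f$metric_S >= 0 && f$metric_S <= 1)
  # the 1 um and 6 um bead classes (2 px and ~12 px at 0.254 um/px)
  sc <- render_scene(data.frame(x = c(-8, 6), y = c(-5, 6), z = 0,
                                radius = c(2, 12) * 130 / 512))
  f2 <- detect_circles(preprocess(sc$left, 0.25, sc$kernel, 10))
  f2 <- f2[order(f2$r), ]
  expect_equal(nrow(f2), 2)
  expect_lt(f2$r[1], 5)                               # small-bead class
  expect_gt(f2$r[2], 8)                               # large-bead class
})

test_that("match_features implements the Eq.-1 cost and its edge cases", {
  one <- data.frame(id = 1L, x = 50, y = 50, r = 5, metric_S = 0.7,
                    energy_E = 100)
  m <- match_features(one, one, 20, 3)
  expect_equal(m$cost_delta, -0.7)                    # dE = dy = 0 -> -S
  expect_equal(m$delta_E, 0)
  expect_equal(m$disparity_px, 0)
  empty <- one[0, ]
  m0 <- match_features(one, empty, 20, 3)
  expect_equal(nrow(m0), 0)
  expect_equal(attr(m0, "unmatched_left"), 1L)
  # disparity sign: left x greater than right -> positive
  right <- one; right$x <- 45
  expect_equal(match_features(one, right, 20, 3)$disparity_px, 5)
  # epipolar and disparity gates exclude candidates
  far <- one; far$y <- 60
  expect_equal(nrow(match_features(one, far, 20, 3)), 0)
})

test_that("greedy and global matching agree with the exhaustive oracle", {
  # contention-light sets: greedy == global == per-left minimum
  for (seed in 1:4) {
    l <- random_features(6, seed, spread_y = 120)
    r <- random_features(7, seed + 100, spread_y = 120)
    r$y <- l$y[1:7 %% 6 + 1] + runif(7, -2, 2)       # near distinct lefts
    mg <- match_features(l, r, 60, 3)
    mo <- oracle_assign(l, r, 60, 3)
    mb <- match_features(l, r, 60, 3, method = "global")
    if (is.null(mo)) {
      expect_equal(nrow(mg), 0)
      next
    }
    expect_equal(nrow(mb), nrow(mo))
    expect_equal(sum(mb$cost_delta), sum(mo$cost), tolerance = 1e-12)
    expect_equal(sum(mg$cost_delta), sum(mo$cost), tolerance = 1e-12)
  }
  # contentious sets (many shared candidates): global == oracle exactly
  for (seed in 11:14) {
    l <- random_features(8, seed, spread_y = 12)
    r <- random_features(9, seed + 50, spread_y = 12)
    mo <- oracle_assign(l, r, 100, 6)
    mb <- match_features(l, r, 100, 6, method = "global")
    expect_equal(nrow(mb), nrow(mo))
    expect_equal(sum(mb$cost_delta), sum(mo$cost), tolerance = 1e-12)
    # greedy never beats the optimum and matches as many features
    mg <- match_features(l, r, 100, 6)
    expect_equal(nrow(mg), nrow(mo))
    expect_gte(sum(mg$cost_delta), sum(mo$cost) - 1e-12)
  }
})

test_that("triangulate converts matches to object depths", {
  geom <- stereo_geometry(2.5, pixel_size = 0.254)
  l <- data.frame(id = 1:3, x = c(10, 50, 90), y = c(20, 20, 20), r = 3,
                  metric_S = 0.8, energy_E = c(5, 50, 500))
  attr(l, "img_dim") <- c(101L, 101L)
  r <- l; r$x <- l$x - c(0, 4, 8)
  m <- match_features(l, r, 20, 3)
  d <- triangulate(m, l, geom)
  expect_equal(d$z[d$id == 1], 0)
  expect_equal(d$z, c(0, 4, 8) * 0.254 / (2 * tan(1.25 * pi / 180)),
               tolerance = 1e-12)
  expect_true(all(d$matched))
  # unmatched left features flagged, not dropped
  m2 <- match_features(l, r[1:2, ], 20, 3)
  d2 <- triangulate(m2, l, geom)
  expect_equal(sum(d2$matched), 2)
  expect_true(is.na(d2$z[!d2$matched]))
  expect_equal(d2$x, (l$x - 51) * 0.254)              # centred um coords
})

test_that("depths_from_stack recovers bead depths from a rendered stack", {
  fr <- small_frame()
  k <- test_kernel()
  beads <- data.frame(x = c(-6, 5), y = c(4, -3), z = c(-8.2, 12.6),
                      radius = c(3, 0.5))
  ph <- manual_phantom(beads)
  st <- render_zstack(ph, fr, k, z_spacing = 1, z_range = c(-20, 20))
  gt <- ground_truth_table(ph, default_geom(), fr)
  feats <- data.frame(id = 1:2, x = gt$col_left - gt$disparity_px / 2,
                      y = gt$row, r = beads$radius / fr$pixel_size,
                      metric_S = 1, energy_E = 1)
  d <- depths_from_stack(st, feats, refine = FALSE)
  expect_lt(max(abs(d$z - beads$z)), 1)               # within z_spacing
  dr <- depths_from_stack(st, feats, refine = TRUE)
  expect_lt(max(abs(dr$z - beads$z)), 0.6)            # refinement helps
  # tie-break: two identical adjacent planes -> lower z
  vol <- array(0, c(9, 9, 4))
  vol[5, 5, 2] <- 1; vol[5, 5, 3] <- 1
  stack <- list(values = vol, z = c(0, 1, 2, 3))
  ft <- data.frame(id = 1, x = 5, y = 5, r = 2, metric_S = 1, energy_E = 1)
  expect_equal(depths_from_stack(stack, ft, refine = FALSE)$z, 1)
  # out-of-bounds feature flagged, not an error
  fo <- data.frame(id = 1, x = 50, y = 5, r = 2, metric_S = 1, energy_E = 1)
  do <- depths_from_stack(stack, fo)
  expect_false(do$in_bounds)
  expect_true(is.na(do$z))
})

test_that("evaluate_depths: fractions, sigma fit, monotonicity", {
  tr <- data.frame(id = 1:4, z = c(10, 20, 30, 40))
  perfect <- data.frame(id = 1:4, z = tr$z, matched = TRUE)
  st <- evaluate_depths(perfect, tr)
  expect_equal(unname(st$fraction_within), c(1, 1))
  expect_equal(st$sigma_fit, 0, tolerance = 1e-9)
  rec <- data.frame(id = 1:4, z = tr$z + c(1, 1, 3, 6), matched = TRUE)
  st2 <- evaluate_depths(rec, tr, thresholds = c(2, 5))
  expect_equal(unname(st2$fraction_within), c(0.5, 0.75))
  # known symmetric error set: fitted sigma near its standard deviation
  set.seed(4)
  errs <- rep(c(-3, -2, -1, 0, 1, 2, 3), times = c(2, 6, 14, 18, 14, 6, 2))
  trn <- data.frame(id = seq_along(errs), z = 50)
  rcn <- data.frame(id = seq_along(errs), z = 50 + errs, matched = TRUE)
  st3 <- evaluate_depths(rcn, trn, thresholds = c(1, 2, 5))
  expect_equal(st3$sigma_fit, stats::sd(errs), tolerance = 0.1)
  expect_true(all(diff(st3$fraction_within) >= 0))    # monotone
  expect_error(evaluate_depths(data.frame(id = 99, z = 1), tr), "ids")
  # fewer than 3 matched: sigma undefined
  st4 <- evaluate_depths(perfect[1:2, ], tr)
  expect_true(is.na(st4$sigma_fit))
})
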