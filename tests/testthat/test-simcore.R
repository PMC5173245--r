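# Synthetic-data engine: phantoms, forward rendering, noise, interlacing,
# ground truth, z-stacks.

test_that("make_phantom: determinism, emptiness, separation", {
  expect_equal(nrow(make_phantom(0)$beads), 0)
  p1 <- make_phantom(25, seed = 7)
  p2 <- make_phantom(25, seed = 7)
  expect_identical(p1$beads, p2$beads)
  expect_false(identical(p1$beads, make_phantom(25, seed = 8)$beads))
  # exhaustive pairwise lateral separation check (87 beads, 3 um floor)
  ph <- make_phantom(87, extent = c(130, 130, 90), min_separation = 3,
                     seed = 3)
  b <- ph$beads
  d <- as.matrix(stats::dist(b[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), 3)
  expect_true(all(abs(b$z) <= 45))
  expect_setequal(unique(b$radius), c(0.5, 3.0))
  expect_error(make_phantom(500, extent = c(20, 20, 10), min_separation = 5,
                            max_tries = 50), "could not place")
})

test_that("render_view geometry matches the closed-form disparity", {
  geom <- default_geom()
  sc <- render_scene(data.frame(x = 3, y = -5, z = 20, radius = 3))
  dl <- centre_of_mass(sc$left); dr <- centre_of_mass(sc$right)
  pred <- disparity_from_depth_geometry(20, geom)
  expect_equal(dl[["x"]] - dr[["x"]], pred, tolerance = 0.5 / pred)
  expect_equal(dl[["y"]], dr[["y"]], tolerance = 0.05)
  # z = 0 bead: identical centroids in both views
  sc0 <- render_scene(data.frame(x = -2, y = 4, z = 0, radius = 0.5))
  expect_equal(centre_of_mass(sc0$left), centre_of_mass(sc0$right),
               tolerance = 1e-9)
  # empty phantom renders to zero
  fr <- small_frame(64)
  expect_equal(render_view(make_phantom(0), "left", geom, fr,
                           test_kernel()),
               matrix(0, 64, 64))
  expect_error(render_view(make_phantom(0), "left", geom,
                           frame_geometry(8, 8),
                           matrix(1, 21, 21) / 441), "kernel")
})

test_that("brightness is linear and views are nonnegative", {
  sc1 <- render_scene(data.frame(x = 0, y = 0, z = 10, radius = 3,
                                 brightness = 1))
  sc2 <- render_scene(data.frame(x = 0, y = 0, z = 10, radius = 3,
                                 brightness = 2))
  expect_equal(sc2$left, 2 * sc1$left, tolerance = 1e-12)
  expect_true(all(sc1$left >= 0))
})

test_that("add_noise: determinism, zero image, large-photon limit", {
  img <- matrix(runif(64 * 64), 64)
  expect_identical(add_noise(img, 100, seed = 5), add_noise(img, 100, seed = 5))
  expect_equal(add_noise(matrix(0, 8, 8), 100), matrix(0, 8, 8))
  big <- add_noise(img, 1e6, seed = 1)
  rel <- sqrt(mean((big / 1e6 * max(img) - img)^2)) / mean(img)
  expect_lt(rel, 0.005)
})

test_that("interlace/deinterlace are exact inverses with the stated layout", {
  fr <- frame_geometry(n_fast = 4, m_slow = 4)
  l <- matrix(1, 4, 4); r <- matrix(2, 4, 4)
  raw <- interlace_views(l, r, fr)
  expect_equal(dim(raw$values), c(8, 4))              # 2M x N
  expect_true(all(raw$values[seq(1, 8, 2), ] == 1))   # odd rows left
  expect_true(all(raw$values[seq(2, 8, 2), ] == 2))
  l2 <- matrix(rnorm(12 * 8), 12, 8)                  # N=12, M=8
  r2 <- matrix(rnorm(12 * 8), 12, 8)
  fr2 <- frame_geometry(n_fast = 12, m_slow = 8)
  raw2 <- interlace_views(l2, r2, fr2)
  expect_equal(dim(raw2$values), c(16, 12))
  pair <- deinterlace(raw2, 2.5)
  expect_identical(pair$left, l2)
  expect_identical(pair$right, r2)
  expect_error(interlace_views(l2, r2[, 1:4], fr2), "mismatch")
})

test_that("ground truth table has exact disparities and rendering-accurate centroids", {
  geom <- default_geom()
  fr <- small_frame()
  beads <- data.frame(x = c(-6, 4, 0), y = c(-4, 7, 0), z = c(-15, 0, 20),
                      radius = c(3, 0.5, 3))
  ph <- manual_phantom(beads)
  gt <- ground_truth_table(ph, geom, fr)
  expect_equal(gt$disparity_px,
               2 * beads$z * tan(1.25 * pi / 180) / fr$pixel_size,
               tolerance = 1e-12)
  expect_equal(gt$disparity_px[2], 0)
  # predicted centroids vs rendered centroids within 0.5 px per view
  k <- test_kernel()
  for (i in seq_len(3)) {
    one <- manual_phantom(beads[i, , drop = FALSE])
    cl <- centre_of_mass(render_view(one, "left", geom, fr, k))
    cr <- centre_of_mass(render_view(one, "right", geom, fr, k))
    expect_lt(abs(cl[["x"]] - gt$col_left[i]), 0.5)
    expect_lt(abs(cr[["x"]] - gt$col_right[i]), 0.5)
    expect_lt(abs(cl[["y"]] - gt$row[i]), 0.5)
  }
})

test_that("z-stack: plane maxima at bead depths, projection consistency", {
  fr <- small_frame()
  k <- test_kernel()
  ph <- manual_phantom(data.frame(x = 3, y = -5, z = 11.3, radius = 3))
  st <- render_zstack(ph, fr, k, z_spacing = 1, z_range = c(0, 20))
  peak_plane <- which.max(apply(st$values, 3, max))
  expect_lt(abs(st$z[peak_plane] - 11.3), 1)          # nearest plane wins
  # sum over planes equals the untilted EDF projection (same kernel)
  edf <- conv2_fft(tpstereo:::render_projection(ph, fr, 0), k)
  expect_lt(max(abs(apply(st$values, c(1, 2), sum) - edf)) / max(edf), 0.02)
  # empty phantom -> zero stack
  st0 <- render_zstack(make_phantom(0), frame_geometry(16, 16), k,
                       z_spacing = 5, z_range = c(-10, 10))
  expect_equal(sum(st0$values), 0)
})

test_that("translated phantoms move the rendered centroid accordingly", {
  geom <- default_geom()
  fr <- small_frame()
  k <- test_kernel()
  ph <- manual_phantom(data.frame(x = -3, y = 2, z = 5, radius = 3))
  v <- c(1.0, 0.5, 0)                                 # um per frame
  c0 <- centre_of_mass(render_view(ph, "left", geom, fr, k))
  c1 <- centre_of_mass(render_view(translate_phantom(ph, v), "left", geom,
                                   fr, k))
  expect_lt(abs((c1[["x"]] - c0[["x"]]) - v[1] / fr$pixel_size), 0.5)
  expect_lt(abs((c1[["y"]] - c0[["y"]]) - v[2] / fr$pixel_size), 0.5)
})
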