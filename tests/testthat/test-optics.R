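# Scalar-diffraction optics: FWHM measurement, closed-form Bessel oracle,
# tilt geometry, pupil construction, propagated focal volumes.

test_that("measure_fwhm matches closed forms and rejects bad profiles", {
  x <- seq(-6, 6, by = 0.01)
  g <- exp(-x^2 / 2)                      # sigma = 1
  expect_equal(measure_fwhm(g, x = x)$fwhm, 2 * sqrt(2 * log(2)),
               tolerance = 0.001 / 2.3548)
  tri <- pmax(1 - abs(seq(-2, 2, by = 0.01)), 0)
  expect_equal(measure_fwhm(tri, x = seq(-2, 2, by = 0.01))$fwhm, 1,
               tolerance = 1e-9)
  expect_error(measure_fwhm(seq(0, 1, 0.1)), "end point")
  expect_error(measure_fwhm(c(0.9, 1, 0.95, 0.92, 0.91)), "crossing")
})

test_that("bessel_closed_form: normalisation, FWHM root, scaling law", {
  cfg <- optical_config()
  bc <- bessel_closed_form(0.30, cfg, r_max = 2)
  expect_equal(bc$profile[1], 1)
  # independent 1D root-find oracle: J0(x*) = 2^(-1/4)
  xstar <- uniroot(function(x) besselJ(x, 0) - 2^(-0.25), c(0.3, 1.5),
                   tol = 1e-12)$root
  expect_equal(xstar, 0.8145, tolerance = 1e-3)
  prof2 <- c(rev(bc$profile[-1]), bc$profile)
  xax <- c(-rev(bc$r[-1]), bc$r)
  fw <- measure_fwhm(prof2, x = xax)$fwhm
  expect_equal(fw, 2 * xstar / bc$k_r, tolerance = 1e-3)
  bc2 <- bessel_closed_form(0.60, cfg, r_max = 1)
  prof2b <- c(rev(bc2$profile[-1]), bc2$profile)
  fw2 <- measure_fwhm(prof2b, x = c(-rev(bc2$r[-1]), bc2$r))$fwhm
  expect_equal(fw / fw2, 2, tolerance = 1e-3)  # doubling NA halves FWHM
})

test_that("tilt angle/shift are exact inverses with the stated form", {
  cfg <- optical_config()
  expect_equal(tilt_angle_from_shift(0, cfg), 0)
  shift <- 1.33 * sin(2.5 * pi / 180)
  expect_equal(shift, 0.0580, tolerance = 1e-3)
  expect_equal(tilt_angle_from_shift(shift, cfg), 2.5, tolerance = 1e-12)
  for (s in c(-0.4, -0.058, 0.01, 0.3)) {
    expect_equal(shift_from_tilt_angle(tilt_angle_from_shift(s, cfg), cfg),
                 s, tolerance = 1e-12)
  }
  expect_error(tilt_angle_from_shift(1.4, cfg), "medium_index")
})

test_that("optical_config calibration hits its lateral/axial anchors", {
  cfg <- optical_config()
  # annulus_na from the 650 nm J0^4 anchor
  bc <- bessel_closed_form(cfg$annulus_na, cfg, r_max = 1)
  prof2 <- c(rev(bc$profile[-1]), bc$profile)
  fw <- measure_fwhm(prof2, x = c(-rev(bc$r[-1]), bc$r))$fwhm
  expect_equal(fw, 0.650, tolerance = 1e-3)
  # invariant violations
  expect_error(optical_config(annulus_na = 0.9, annulus_width_na = 0.3),
               "annulus")
  expect_error(optical_config(annulus_shift = 0.8), "pupil")
})

test_that("pupil_field geometry: symmetry, ring radius, modes", {
  cfg <- optical_config(annulus_na = 0.30, annulus_width_na = 0.03)
  pup <- pupil_field(cfg, "annulus", grid_n = 256)
  a <- Mod(pup$values)
  # radial symmetry about the grid centre (FFT axis: row 1 has no partner)
  expect_equal(a[-1, ], a[256:2, ], tolerance = 1e-12)
  expect_equal(a, t(a), tolerance = 1e-12)
  # ring peak at radius 0.30 NA along the +x axis
  ctr <- 129
  prof <- a[, ctr]
  expect_equal(abs(pup$na_axis[which.max(prof[ctr:256]) + ctr - 1]), 0.30,
               tolerance = pup$dna)
  pupf <- pupil_field(cfg, "full_gaussian", grid_n = 128)
  af <- Mod(pupf$values)
  rho <- sqrt(outer(pupf$na_axis^2, pupf$na_axis^2, `+`))
  expect_true(all(af[rho > 1.0 + 2 * pupf$dna] == 0))
  expect_true(all(af[rho < 0.9] == 1))
  # partial gaussian: 1/e^2 intensity at the ring radius
  pupp <- pupil_field(cfg, "partial_gaussian", grid_n = 256)
  ap <- Mod(pupp$values)
  i0 <- ap[129, 129]^2
  iring <- ap[129, which.min(abs(pupp$na_axis - 0.30))]^2
  expect_equal(iring / i0, exp(-2), tolerance = 0.05)
})

test_that("focal_volume: mirror symmetry and per-plane energy conservation", {
  cfg <- optical_config(annulus_width_na = 0.03)
  pup <- pupil_field(cfg, "annulus", grid_n = 256, na_halfspan = 1.2)
  psf <- suppressWarnings(
    focal_volume(pup, cfg, extent = c(10, 10, 40), sampling = c(0.325, 0.325, 10)))
  pl <- psf$values[, , 3]
  expect_equal(pl, pl[nrow(pl):1, ], tolerance = 1e-6)  # x mirror at shift 0
  expect_true(all(psf$values >= 0))
  expect_equal(max(psf$values), 1)
  # energy: per-plane integral of |E|^2 (before squaring) is conserved
  # exactly by the unitary propagator; check via plane intensities
  ax <- pup$na_axis; g <- length(ax)
  rho2 <- outer(ax^2, ax^2, `+`)
  kz <- matrix(0, g, g)
  prop <- rho2 < cfg$medium_index^2
  kz[prop] <- 2 * pi / cfg$wavelength * sqrt(cfg$medium_index^2 - rho2[prop])
  a <- pup$values; a[!prop] <- 0
  en <- vapply(c(-20, 0, 20), function(z) {
    sum(Mod(stats::fft(a * exp(1i * kz * z), inverse = TRUE))^2)
  }, numeric(1))
  expect_lt((max(en) - min(en)) / mean(en), 0.01)
  suppressWarnings(
    expect_error(focal_volume(structure(list(values = matrix(0, 64, 64) + 0i,
                                             na_axis = seq(-1, 1, length.out = 64),
                                             dna = 2 / 64, na_halfspan = 1,
                                             config = cfg),
                                        class = "pupil_field"), cfg),
                 "zero"))
})

test_that("axial profile: 160 um calibration anchor and rounded-tip oscillation", {
  cfg <- optical_config()
  z <- seq(-220, 220, by = 1)
  ax <- axial_profile_on_axis(cfg, z)
  fw <- measure_fwhm(ax, x = z)$fwhm
  expect_equal(fw, 160, tolerance = 0.10)
  n_max <- function(p) sum(diff(sign(diff(p))) == -2)
  expect_lte(n_max(ax), 1)                       # smooth envelope
  axt <- axial_profile_on_axis(cfg, z, mode = "rounded_tip")
  expect_gte(n_max(axt), 3)                      # tip-interference fringes
})

test_that("tilted annulus produces the asin(shift/n) focal-line slope", {
  shift <- shift_from_tilt_angle(2.5, optical_config())
  cfg <- optical_config(annulus_width_na = 0.012, annulus_shift = shift)
  pup <- pupil_field(cfg, "annulus", grid_n = 512, na_halfspan = 1.2)
  psf <- suppressWarnings(
    focal_volume(pup, cfg, extent = c(30, 6, 50), sampling = c(0.325, 0.325, 5)))
  ct <- psf_centroid_track(psf, window = 2)
  slope <- stats::coef(stats::lm(cx ~ z, ct))[[2]]
  expect_equal(slope, tan(2.5 * pi / 180), tolerance = 0.02)
  expect_equal(psf$tilt_angle, 2.5, tolerance = 1e-9)
})

test_that("PSF volume TIFF export round-trips values and metadata", {
  cfg <- optical_config(annulus_width_na = 0.03)
  pup <- pupil_field(cfg, "annulus", grid_n = 128, na_halfspan = 1.2)
  psf <- suppressWarnings(
    focal_volume(pup, cfg, extent = c(8, 8, 20), sampling = c(0.325, 0.325, 10)))
  tf <- tempfile(fileext = ".tif")
  write_psf_volume(psf, tf)
  pages <- read_tiff(tf)
  expect_length(pages, dim(psf$values)[3])
  expect_equal(pages[[2]], psf$values[, , 2], tolerance = 1e-6)
  meta <- jsonlite::fromJSON(sub("\\.tif$", ".json", tf))
  expect_equal(meta$dz, psf$dz_vox)
})
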