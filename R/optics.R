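# Scalar-diffraction model of the excitation path: annular (axicon-derived)
# pupils at the objective back focal plane, tilted Bessel-Gauss focal volumes
# computed with a band-limited angular-spectrum propagator, Gaussian reference
# foci, and FWHM measurement.
#
# Coordinates: pupil positions are expressed in NA units, nu = n*sin(theta)
# (direction cosines times the immersion index), so the pupil edge sits at
# nu = na_objective.  The axial wavenumber is kz = (2*pi/lambda)*sqrt(n^2-nu^2).
# Laterally shifting an annulus by `annulus_shift` (NA units) tilts the focal
# line by theta = asin(annulus_shift / medium_index).

#' Optical configuration of the excitation path
#'
#' Bundles wavelength, objective NA, immersion index, axicon parameters and
#' the annular-pupil geometry (ring centre NA, radial width, lateral shift).
#' The ring geometry defaults are calibrated, not measured: `annulus_na` is
#' chosen so the ideal-Bessel `J0^4` lateral profile has a 0.65 um FWHM and
#' `annulus_width_na` so the two-photon axial FWHM is 160 um (see
#' [calibrate_annulus_na()] and [calibrate_annulus_width()]).
#'
#' @param wavelength Excitation wavelength in um (default 0.780).
#' @param na_objective Objective numerical aperture (default 1.0).
#' @param focal_length Objective reference focal length in um (default 9000,
#'   i.e. a 180 mm tube lens with a 20x objective).
#' @param medium_index Immersion refractive index (default 1.33, water).
#' @param axicon_base_angle Axicon base angle in degrees (default 1.15).
#' @param axicon_index Axicon glass refractive index (default 1.45).
#' @param annulus_na Centre NA of the ring at the back focal plane.
#'   `NULL` (default) uses the 0.65-um lateral calibration.
#' @param annulus_width_na Radial half-width of the ring in NA units (1/e of
#'   amplitude, 1/e^2 of intensity).  `NULL` (default) uses the 160-um axial
#'   calibration.
#' @param annulus_shift Lateral displacement of the ring in NA units; tilts
#'   the focal line by `asin(annulus_shift/medium_index)`.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength = 0.780,
                           na_objective = 1.0,
                           focal_length = 9000,
                           medium_index = 1.33,
                           axicon_base_angle = 1.15,
                           axicon_index = 1.45,
                           annulus_na = NULL,
                           annulus_width_na = NULL,
                           annulus_shift = 0) {
  if (wavelength <= 0) stop("wavelength must be > 0")
  if (na_objective <= 0 || na_objective > medium_index) {
    stop("na_objective must be in (0, medium_index]")
  }
  if (is.null(annulus_na)) {
    annulus_na <- calibrate_annulus_na(0.65, wavelength)
  }
  if (is.null(annulus_width_na)) {
    annulus_width_na <- calibrate_annulus_width(160, annulus_na,
                                                wavelength, medium_index)
  }
  cfg <- structure(list(
    wavelength = wavelength,
    na_objective = na_objective,
    focal_length = focal_length,
    medium_index = medium_index,
    axicon_base_angle = axicon_base_angle,
    axicon_index = axicon_index,
    annulus_na = annulus_na,
    annulus_width_na = annulus_width_na,
    annulus_shift = annulus_shift
  ), class = "optical_config")
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  with(cfg, {
    outer_edge <- annulus_na + annulus_width_na / 2
    if (!(annulus_na > 0) || outer_edge > na_objective) {
      stop("annulus ring must satisfy 0 < annulus_na + width/2 <= na_objective")
    }
    if (abs(annulus_shift) + outer_edge > na_objective) {
      stop("shifted annulus exceeds the objective pupil (NA ",
           round(abs(annulus_shift) + outer_edge, 3), " > ", na_objective, ")")
    }
  })
  invisible(cfg)
}

#' Calibrate the annulus centre NA from a target lateral FWHM
#'
#' Solves for the ring NA whose ideal-Bessel two-photon profile
#' `J0(k_r r)^4` has the requested lateral FWHM.  The half-maximum argument
#' `x*` solves `J0(x*) = 2^(-1/4)` (root-found, approximately 0.8145), and
#' `FWHM = 2 x* / k_r` with `k_r = 2*pi*annulus_na/lambda`.
#'
#' @param lateral_fwhm Target two-photon lateral FWHM in um.
#' @param wavelength Wavelength in um.
#' @return Ring centre NA (dimensionless).
#' @export
calibrate_annulus_na <- function(lateral_fwhm, wavelength = 0.780) {
  xstar <- j0_half_max_arg()
  xstar * wavelength / (pi * lateral_fwhm)
}

# x* with J0(x*)^4 = 1/2, i.e. J0(x*) = 2^(-1/4).
j0_half_max_arg <- function() {
  stats::uniroot(function(x) besselJ(x, 0) - 2^(-0.25),
                 c(0.3, 1.5), tol = 1e-12)$root
}

#' Calibrate the annulus radial width from a target axial FWHM
#'
#' For a Gaussian ring of amplitude `exp(-((nu-nu0)/w)^2)` the on-axis
#' two-photon intensity envelope is `exp(-z^2 * D^2 * w^2)` with
#' `D = dkz/dnu = (2*pi/lambda) * nu0 / sqrt(n^2 - nu0^2)` (first-order
#' expansion of kz across the ring), giving
#' `FWHM_z = 2*sqrt(log 2) / (D * w)`.  This closed form is inverted for `w`;
#' the consistency of the resulting simulated axial FWHM is asserted in the
#' test suite.
#'
#' @param axial_fwhm Target two-photon axial FWHM in um.
#' @param annulus_na Ring centre NA.
#' @param wavelength Wavelength in um.
#' @param medium_index Immersion index.
#' @return Ring radial half-width in NA units (1/e amplitude).
#' @export
calibrate_annulus_width <- function(axial_fwhm, annulus_na,
                                    wavelength = 0.780, medium_index = 1.33) {
  d <- (2 * pi / wavelength) * annulus_na /
    sqrt(medium_index^2 - annulus_na^2)
  2 * sqrt(log(2)) / (d * axial_fwhm)
}

#' Tilt angle of the focal line from the annulus shift
#'
#' A lateral displacement of the annulus at the back focal plane by
#' `annulus_shift` NA units tilts the Bessel focal line by
#' `theta = asin(annulus_shift / medium_index)`.
#'
#' @param annulus_shift Lateral ring displacement in NA units.
#' @param config An [optical_config()].
#' @return Tilt angle in degrees.
#' @export
tilt_angle_from_shift <- function(annulus_shift, config) {
  if (abs(annulus_shift) >= config$medium_index) {
    stop("|annulus_shift| must be < medium_index")
  }
  asin(annulus_shift / config$medium_index) * 180 / pi
}

#' @rdname tilt_angle_from_shift
#' @param tilt_angle Tilt angle in degrees.
#' @export
shift_from_tilt_angle <- function(tilt_angle, config) {
  if (abs(tilt_angle) >= 90) stop("|tilt_angle| must be < 90 degrees")
  config$medium_index * sin(tilt_angle * pi / 180)
}

#' Pupil field at the back focal plane
#'
#' Builds the complex pupil amplitude on a square NA-coordinate grid.
#' Modes:
#' \describe{
#'   \item{annulus}{Gaussian-profile ring of centre NA `annulus_na`, radial
#'     half-width `annulus_width_na`, displaced laterally (+x) by
#'     `annulus_shift`.}
#'   \item{full_gaussian}{uniformly filled pupil out to `na_objective`
#'     (an overfilled, effectively flat-top beam), soft-edged over one grid
#'     sample.}
#'   \item{partial_gaussian}{Gaussian beam whose 1/e^2 intensity diameter
#'     equals the annulus ring diameter `2*annulus_na`.}
#'   \item{rounded_tip}{annulus plus an on-axis leakage term emulating light
#'     passing the rounded apex of a real axicon undeviated; its interference
#'     with the conical wave produces the axial intensity oscillation seen
#'     with physical axicons.  Controlled by `tip_amplitude` and
#'     `tip_width_na`.}
#' }
#'
#' The physical lateral sampling of a focal field computed from this pupil by
#' [focal_volume()] is `dx = lambda / (2*na_halfspan)`, independent of
#' `grid_n`; `grid_n` sets the lateral field of view `grid_n * dx`.
#'
#' @param config An [optical_config()].
#' @param mode One of `"annulus"`, `"full_gaussian"`, `"partial_gaussian"`,
#'   `"rounded_tip"`.
#' @param grid_n Samples per side (>= 64).
#' @param na_halfspan Half-extent of the NA grid.  Defaults to
#'   `1.1 * na_objective`; raise it to refine the focal-plane sampling.
#' @param tip_amplitude Relative amplitude of the rounded-tip leakage beam.
#' @param tip_width_na 1/e half-width (NA units) of the leakage beam.
#' @return An object of class `pupil_field`: list with complex matrix
#'   `values`, grid spacing `dna`, axis `na_axis`, and the generating
#'   `config` and `mode`.
#' @export
pupil_field <- function(config, mode = c("annulus", "full_gaussian",
                                         "partial_gaussian", "rounded_tip"),
                        grid_n = 512, na_halfspan = NULL,
                        tip_amplitude = 0.15, tip_width_na = NULL) {
  mode <- match.arg(mode)
  stopifnot(grid_n >= 64)
  validate_optical_config(config)
  na_halfspan <- na_halfspan %||% (1.1 * config$na_objective)
  dna <- 2 * na_halfspan / grid_n
  ax <- (seq_len(grid_n) - 1 - grid_n / 2) * dna
  nux <- matrix(ax, grid_n, grid_n)
  nuy <- matrix(ax, grid_n, grid_n, byrow = TRUE)
  rho <- sqrt(nux^2 + nuy^2)

  soft_disc <- function(r, radius) {
    # 1-sample anti-aliased edge
    pmin(pmax((radius - r) / dna + 0.5, 0), 1)
  }
  # Tilt = rotation of the angular spectrum on the k-sphere by
  # theta = asin(shift/n) about the y axis.  The ring-centre displacement is
  # n*sin(theta) = annulus_shift, and the beam walks off at exactly
  # tan(theta); a rigid in-plane translation of the ring would instead walk
  # ~ (1 + annulus_na^2/(2 kz^2)) faster (the ring must deform as it tilts).
  beam_rho <- function() {
    n <- config$medium_index
    st <- config$annulus_shift / n
    ct <- sqrt(1 - st^2)
    nuz <- sqrt(pmax(n^2 - rho^2, 0))
    nux_b <- ct * nux - st * nuz
    sqrt(nux_b^2 + nuy^2)
  }
  p <- switch(mode,
    annulus = {
      rs <- beam_rho()
      exp(-((rs - config$annulus_na) / config$annulus_width_na)^2)
    },
    full_gaussian = soft_disc(rho, config$na_objective),
    partial_gaussian = exp(-(rho / config$annulus_na)^2) *
      soft_disc(rho, config$na_objective),
    rounded_tip = {
      rs <- beam_rho()
      tw <- tip_width_na %||% (config$annulus_na / 4)
      exp(-((rs - config$annulus_na) / config$annulus_width_na)^2) +
        tip_amplitude * exp(-(rs / tw)^2)
    }
  )
  # band limit: nothing outside the pupil or beyond homogeneous waves
  p[rho > config$na_objective + dna] <- 0
  if (sum(abs(p)) == 0) stop("pupil field is identically zero")
  structure(list(values = p + 0i, dna = dna, na_axis = ax,
                 na_halfspan = na_halfspan, config = config, mode = mode),
            class = "pupil_field")
}

#' Focal intensity volume by angular-spectrum propagation
#'
#' Propagates the pupil field plane by plane: the field at depth z is the 2D
#' inverse Fourier transform of `P(nu) * exp(i*kz(nu)*z)` with
#' `kz = (2*pi/lambda)*sqrt(n^2 - nu^2)` (evanescent components discarded —
#' band-limited angular spectrum).  Returns the two-photon excitation PSF,
#' `PSF2p = (I / max I)^2`, cropped to the requested extent.
#'
#' Lateral sampling is fixed by the pupil grid (`dx = lambda/(2*na_halfspan)`),
#' so choose `na_halfspan` when building the pupil; a request finer than the
#' pupil provides is an error, a coarser one is honoured by cropping only
#' (no resampling).
#'
#' @param pupil A [pupil_field()].
#' @param config An [optical_config()] (defaults to the pupil's own).
#' @param extent Lengths `c(x, y, z)` in um of the volume to keep, centred on
#'   the focus.
#' @param sampling Lengths `c(dx, dy, dz)` in um; `dx`, `dy` must equal the
#'   pupil-implied sampling within 1%, `dz` is free.
#' @param apodization `"none"` (plain angular spectrum, the default) or
#'   `"sine"` (aplanatic sqrt(cos theta) weighting).
#' @return An object of class `psf_volume`: 3D array `values` (x, y, z),
#'   voxel spacings, axes, and `tilt_angle` (degrees) implied by the pupil
#'   shift.
#' @export
focal_volume <- function(pupil, config = pupil$config,
                         extent = c(20, 20, 400),
                         sampling = NULL,
                         apodization = c("none", "sine")) {
  apodization <- match.arg(apodization)
  stopifnot(inherits(pupil, "pupil_field"))
  lam <- config$wavelength
  n <- config$medium_index
  grid_n <- nrow(pupil$values)
  dx <- lam / (2 * pupil$na_halfspan)
  if (!is.null(sampling)) {
    if (abs(sampling[1] - dx) > 0.01 * dx || abs(sampling[2] - dx) > 0.01 * dx) {
      stop(sprintf(
        "pupil grid implies lateral sampling %.4f um; requested %.4f um. ",
        dx, sampling[1]), "Adjust na_halfspan when building the pupil.")
    }
    dz <- sampling[3]
  } else {
    dz <- max(extent[3] / 100, dx)
  }
  if (dx > lam / 4) {
    warning(sprintf("lateral sampling %.3f um coarser than lambda/4; aliasing likely", dx))
  }
  ax <- pupil$na_axis
  nux <- matrix(ax, grid_n, grid_n)
  nuy <- matrix(ax, grid_n, grid_n, byrow = TRUE)
  rho2 <- nux^2 + nuy^2
  prop <- rho2 < n^2
  kz <- matrix(0, grid_n, grid_n)
  kz[prop] <- (2 * pi / lam) * sqrt(n^2 - rho2[prop])
  a <- pupil$values
  a[!prop] <- 0
  if (apodization == "sine") {
    ct <- matrix(0, grid_n, grid_n)
    ct[prop] <- sqrt(n^2 - rho2[prop]) / n
    a <- a * sqrt(ct)
  }

  xax <- (seq_len(grid_n) - 1 - grid_n / 2) * dx
  keep_x <- which(abs(xax) <= extent[1] / 2 + 1e-9)
  keep_y <- which(abs(xax) <= extent[2] / 2 + 1e-9)
  nz <- max(1L, 2L * floor(extent[3] / (2 * dz)) + 1L)
  zax <- (seq_len(nz) - (nz + 1) / 2) * dz

  vol <- array(0, c(length(keep_x), length(keep_y), nz))
  a0 <- ifftshift2(a)
  kz0 <- ifftshift2(kz)
  for (iz in seq_len(nz)) {
    f <- stats::fft(a0 * exp(1i * kz0 * zax[iz]), inverse = TRUE)
    inten <- Mod(fftshift2(f))^2
    vol[, , iz] <- inten[keep_x, keep_y]
  }
  mx <- max(vol)
  if (mx <= 0) stop("propagated field has zero intensity")
  psf2p <- (vol / mx)^2
  structure(list(values = psf2p,
                 dx = dx, dy = dx, dz_vox = dz,
                 x_axis = xax[keep_x], y_axis = xax[keep_y], z_axis = zax,
                 tilt_angle = tilt_angle_from_shift(config$annulus_shift,
                                                    config),
                 config = config),
            class = "psf_volume")
}

#' On-axis two-photon axial profile of a radially symmetric pupil
#'
#' For an unshifted, radially symmetric pupil the on-axis field reduces to a
#' 1D Hankel-type integral `E(z) = int A(nu) exp(i kz(nu) z) nu dnu`, which
#' this evaluates by trapezoidal quadrature on a fine `nu` grid — far finer
#' than the 2D grid can afford, which matters for the narrow calibrated ring.
#' Returns `PSF2p(z)` on axis, normalised to 1 at its maximum.
#'
#' @param config An [optical_config()] (`annulus_shift` must be 0).
#' @param z Vector of axial positions in um.
#' @param mode Pupil mode as in [pupil_field()].
#' @param n_nu Number of radial quadrature nodes.
#' @param tip_amplitude,tip_width_na Rounded-tip model parameters.
#' @return Numeric vector of on-axis `PSF2p` values.
#' @export
axial_profile_on_axis <- function(config, z, mode = "annulus", n_nu = 4000,
                                  tip_amplitude = 0.15, tip_width_na = NULL) {
  if (config$annulus_shift != 0) {
    stop("on-axis profile requires an unshifted (symmetric) pupil")
  }
  lam <- config$wavelength
  n <- config$medium_index
  nu <- seq(0, config$na_objective, length.out = n_nu)
  amp <- switch(mode,
    annulus = exp(-((nu - config$annulus_na) / config$annulus_width_na)^2),
    full_gaussian = rep(1, n_nu),
    partial_gaussian = exp(-(nu / config$annulus_na)^2),
    rounded_tip = {
      tw <- tip_width_na %||% (config$annulus_na / 4)
      exp(-((nu - config$annulus_na) / config$annulus_width_na)^2) +
        tip_amplitude * exp(-(nu / tw)^2)
    },
    stop("unknown mode: ", mode)
  )
  kz <- (2 * pi / lam) * sqrt(pmax(n^2 - nu^2, 0))
  w <- amp * nu
  # trapezoid weights
  w[c(1, n_nu)] <- w[c(1, n_nu)] / 2
  e <- vapply(z, function(zz) sum(w * exp(1i * kz * zz)), complex(1))
  i2 <- Mod(e)^4
  i2 / max(i2)
}

#' Ideal Bessel-beam two-photon lateral profile (closed form)
#'
#' The infinitely thin annulus of ring NA `ring_na` produces a Bessel beam
#' with lateral field `J0(k_r r)`, `k_r = 2*pi*ring_na/lambda`; two-photon
#' excitation follows `J0(k_r r)^4`.  Serves as the analytic oracle for the
#' numerically propagated annular PSF.
#'
#' @param ring_na Ring NA (> 0).
#' @param config An [optical_config()] (supplies the wavelength).
#' @param r_max Maximum radius in um.
#' @param n_samples Number of radial samples.
#' @return List with `r` (um) and `profile` (PSF2p, 1 at r = 0).
#' @export
bessel_closed_form <- function(ring_na, config, r_max = 3, n_samples = 2048) {
  stopifnot(ring_na > 0)
  kr <- 2 * pi * ring_na / config$wavelength
  r <- seq(0, r_max, length.out = n_samples)
  list(r = r, profile = besselJ(kr * r, 0)^4, k_r = kr)
}

#' Full width at half maximum of a sampled profile
#'
#' Locates the global maximum and linearly interpolates the half-maximum
#' crossings nearest the peak on either side.
#'
#' @param profile Numeric vector with a unique interior global maximum.
#' @param spacing Sample spacing (um); or supply `x` explicitly.
#' @param x Optional sample positions (overrides `spacing`).
#' @param axis Label stored in the result.
#' @return List of class `fwhm_result`: `fwhm`, `peak_position`, `axis`.
#' @export
measure_fwhm <- function(profile, spacing = 1, x = NULL, axis = "lateral-x") {
  n <- length(profile)
  if (n < 3) stop("profile too short")
  if (is.null(x)) x <- (seq_len(n) - 1) * spacing
  ipk <- which.max(profile)
  if (ipk == 1 || ipk == n) stop("profile maximum at an end point")
  half <- profile[ipk] / 2
  below_l <- which(profile[1:(ipk - 1)] < half)
  below_r <- which(profile[(ipk + 1):n] < half) + ipk
  if (length(below_l) == 0 || length(below_r) == 0) {
    stop("no half-maximum crossing on one side (monotone profile?)")
  }
  il <- max(below_l)                      # crossing between il and il+1
  ir <- min(below_r)                      # crossing between ir-1 and ir
  xl <- interp_crossing(x, profile, il, half)
  xr <- interp_crossing(x, profile, ir - 1, half)
  structure(list(fwhm = xr - xl, peak_position = x[ipk], axis = axis),
            class = "fwhm_result")
}

#' Lateral profile of a PSF volume through the focus
#'
#' Extracts the intensity profile along x (or y) through the voxel with the
#' global maximum, at that voxel's z plane.
#'
#' @param psf A `psf_volume`.
#' @param axis `"x"` or `"y"`.
#' @return List with `x` (positions, um) and `profile`.
#' @export
lateral_profile <- function(psf, axis = c("x", "y")) {
  axis <- match.arg(axis)
  idx <- arrayInd(which.max(psf$values), dim(psf$values))
  if (axis == "x") {
    list(x = psf$x_axis, profile = psf$values[, idx[2], idx[3]])
  } else {
    list(x = psf$y_axis, profile = psf$values[idx[1], , idx[3]])
  }
}

#' Per-plane lateral centroid of a PSF volume
#'
#' Returns the intensity-weighted centroid x(z) of each z plane, used to
#' verify that a shifted annulus tilts the focal line by the predicted angle
#' (slope of x(z) = tan(theta)).  With `window` set, the centroid is
#' restricted to pixels within that radius (um) of the plane's intensity
#' maximum, tracking the beam core and suppressing side-lobe and windowing
#' bias at the volume edges.
#'
#' @param psf A `psf_volume`.
#' @param window Optional radius in um for a peak-centred windowed centroid.
#' @return Data frame with `z` and `cx` (um).
#' @export
psf_centroid_track <- function(psf, window = NULL) {
  nz <- dim(psf$values)[3]
  cx <- vapply(seq_len(nz), function(iz) {
    pl <- psf$values[, , iz]
    if (!is.null(window)) {
      pk <- arrayInd(which.max(pl), dim(pl))
      d2 <- outer((psf$x_axis - psf$x_axis[pk[1]])^2,
                  (psf$y_axis - psf$y_axis[pk[2]])^2, `+`)
      pl <- pl * (d2 <= window^2)
    }
    sum(pl * psf$x_axis) / sum(pl)
  }, numeric(1))
  data.frame(z = psf$z_axis, cx = cx)
}

#' Write a PSF volume as multi-page TIFF plus sidecar JSON
#'
#' One 32-bit float page per z plane; voxel spacing and tilt recorded in a
#' JSON sidecar next to the TIFF.
#'
#' @param psf A `psf_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_psf_volume <- function(psf, path) {
  pages <- lapply(seq_len(dim(psf$values)[3]), function(iz) psf$values[, , iz])
  write_tiff(pages, path, bits = 32, sample_format = "float")
  meta <- list(dx = psf$dx, dy = psf$dy, dz = psf$dz_vox,
               tilt_angle = psf$tilt_angle,
               nx = dim(psf$values)[1], ny = dim(psf$values)[2],
               nz = dim(psf$values)[3])
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
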