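# Stereo-scanner geometry and timing: frame layout, per-mirror control
# waveforms with line/flyback structure, the volumes-per-second model, and
# the disparity/depth triangulation geometry.
#
# Scan layout: the fast (Y) galvo pair sweeps each line; the slow (X) pair
# steps once per stereo line pair.  Each line position is scanned twice with
# oppositely tilted beams, so a frame of M slow-axis lines contains 2M
# scanned lines, interlaced L,R,L,R...

#' Frame geometry
#'
#' @param n_fast Pixels per line (N), default 512.
#' @param m_slow Lines per view (M), default 512.
#' @param pixel_size Pixel pitch in um; default 130/512 = 0.254 um, from a
#'   130 um field of view at 512 pixels.
#' @param depth_range Imaged depth range in um (default 90).
#' @return Object of class `frame_geometry`.
#' @export
frame_geometry <- function(n_fast = 512L, m_slow = 512L,
                           pixel_size = 130 / 512, depth_range = 90) {
  stopifnot(n_fast >= 1, m_slow >= 1, pixel_size > 0)
  structure(list(n_fast = as.integer(n_fast), m_slow = as.integer(m_slow),
                 pixel_size = pixel_size, depth_range = depth_range),
            class = "frame_geometry")
}

#' Scan timing
#'
#' Line duration `t_line` (equal for left and right lines) and the two
#' flyback intervals during which the view angle switches.  The stereo
#' line-pair rate is `1 / (2*t_line + t_flyback1 + t_flyback2)`.
#'
#' The default operating point is calibrated, not derived: 716.8 stereo line
#' pairs per second reproduces the 1.4 volumes/s full-frame (512-line)
#' figure; the flyback split is then chosen symmetrically around a 0.5 ms
#' line (1 kHz-class galvos).  Pass `pair_rate` to recalibrate, or all three
#' times explicitly.
#'
#' @param t_line Line duration in seconds.
#' @param t_flyback1,t_flyback2 Flyback durations in seconds; defaulted from
#'   `pair_rate` when omitted.
#' @param pair_rate Stereo line pairs per second used to derive the flybacks.
#' @return Object of class `scan_timing`.
#' @export
scan_timing <- function(t_line = 5e-4, t_flyback1 = NULL, t_flyback2 = NULL,
                        pair_rate = 716.8) {
  if (is.null(t_flyback1) || is.null(t_flyback2)) {
    slack <- 1 / pair_rate - 2 * t_line
    if (slack <= 0) stop("pair_rate too high for the given t_line")
    t_flyback1 <- t_flyback1 %||% (slack / 2)
    t_flyback2 <- t_flyback2 %||% (slack - t_flyback1)
  }
  stopifnot(t_line > 0, t_flyback1 > 0, t_flyback2 > 0)
  structure(list(t_line = t_line, t_flyback1 = t_flyback1,
                 t_flyback2 = t_flyback2,
                 stereo_line_pair_rate =
                   1 / (2 * t_line + t_flyback1 + t_flyback2)),
            class = "scan_timing")
}

#' Volumetric imaging rate
#'
#' One volume is one interlaced stereo frame: M stereo line pairs.  The rate
#' is the stereo line-pair rate divided by the number of slow-axis lines, so
#' halving the line count doubles the volume rate.
#'
#' @param frame A [frame_geometry()].
#' @param timing A [scan_timing()].
#' @return Volumes per second.
#' @export
volume_rate <- function(frame, timing) {
  timing$stereo_line_pair_rate / frame$m_slow
}

#' Stereo viewing geometry
#'
#' The full parallax angle `alpha` between the two views (the beams sit at
#' +/- alpha/2 around the optical axis).  The achievable axial resolution is
#' `dz = dx / sin(alpha)` for lateral resolution `dx`.
#'
#' @param parallax_alpha Full angle between the views, degrees (0, 90).
#' @param dx Lateral resolution in um (default 0.77, the measured two-photon
#'   lateral FWHM).
#' @param pixel_size Pixel pitch in um used for triangulation.
#' @return Object of class `stereo_geometry` with `axial_resolution_dz`.
#' @export
stereo_geometry <- function(parallax_alpha = 2.5, dx = 0.77,
                            pixel_size = 130 / 512) {
  if (!(parallax_alpha > 0 && parallax_alpha < 90)) {
    stop("parallax_alpha must be in (0, 90) degrees")
  }
  structure(list(parallax_alpha = parallax_alpha,
                 lateral_resolution_dx = dx,
                 axial_resolution_dz = dx / sin(parallax_alpha * pi / 180),
                 pixel_size = pixel_size),
            class = "stereo_geometry")
}

#' Depth from disparity by triangulation
#'
#' `z = disparity_px * pixel_size / (2 * tan(alpha/2))`.  Sign convention:
#' positive disparity (left-view x greater than right-view x) means the
#' object lies above the zero-disparity reference plane.
#'
#' @param disparity_px Signed disparity in pixels (vectorised).
#' @param geom A [stereo_geometry()].
#' @return Depth(s) in um.
#' @export
depth_from_disparity_geometry <- function(disparity_px, geom) {
  disparity_px * geom$pixel_size /
    (2 * tan(geom$parallax_alpha / 2 * pi / 180))
}

#' @rdname depth_from_disparity_geometry
#' @param z Depth(s) in um.
#' @export
disparity_from_depth_geometry <- function(z, geom) {
  2 * z * tan(geom$parallax_alpha / 2 * pi / 180) / geom$pixel_size
}

#' Stereo-scanner control waveforms
#'
#' Synthesises the four mirror signals over one frame.  Per stereo line pair:
#' a left line (`t_line`), flyback 1 (view switch), a right line (`t_line`),
#' flyback 2 (switch back and slow-axis step).  The fast pair `Y1 = Y2`
#' ramps over each line and flies back between lines; the slow pair holds
#' the line position, with `X2 = X1 + tilt_offset/2` during left lines and
#' `X1 - tilt_offset/2` during right lines, ramping between the two offsets
#' only inside the flyback windows.  Amplitudes are normalised scan angles
#' in [-0.5, 0.5].
#'
#' @param frame A [frame_geometry()].
#' @param timing A [scan_timing()].
#' @param tilt_offset Angle-switch amplitude applied to X2 (normalised scan
#'   angle units).
#' @param sample_rate Samples per second (must resolve a line and both
#'   flybacks).
#' @return Object of class `scan_waveforms`: `t`, `X1`, `X2`, `Y1`, `Y2`,
#'   data frame `lines` (view label, start/end sample of each scanned line).
#' @export
build_waveforms <- function(frame, timing, tilt_offset = 0.02,
                            sample_rate = 2e5) {
  n_line <- round(sample_rate * timing$t_line)
  n_fb1 <- round(sample_rate * timing$t_flyback1)
  n_fb2 <- round(sample_rate * timing$t_flyback2)
  if (n_line < frame$n_fast) {
    stop("sample_rate * t_line must be >= n_fast (one sample per pixel)")
  }
  if (n_fb1 < 1 || n_fb2 < 1) {
    stop("tilt switching interval shorter than one sample at this sample_rate")
  }
  m <- frame$m_slow
  n_pair <- 2 * n_line + n_fb1 + n_fb2
  n_tot <- m * n_pair
  y_line <- seq(-0.5, 0.5, length.out = n_line)
  x_levels <- if (m == 1) 0 else seq(-0.5, 0.5, length.out = m)

  y <- numeric(n_tot)
  x1 <- numeric(n_tot)
  x2off <- numeric(n_tot)
  lines <- vector("list", 2 * m)
  for (i in seq_len(m)) {
    o <- (i - 1) * n_pair
    x_next <- x_levels[min(i + 1, m)]
    idxL <- o + seq_len(n_line)
    idxF1 <- o + n_line + seq_len(n_fb1)
    idxR <- o + n_line + n_fb1 + seq_len(n_line)
    idxF2 <- o + 2 * n_line + n_fb1 + seq_len(n_fb2)
    y[idxL] <- y_line
    y[idxF1] <- seq(0.5, -0.5, length.out = n_fb1)
    y[idxR] <- y_line
    y[idxF2] <- seq(0.5, -0.5, length.out = n_fb2)
    x1[c(idxL, idxF1, idxR)] <- x_levels[i]
    x1[idxF2] <- seq(x_levels[i], x_next, length.out = n_fb2)
    x2off[idxL] <- tilt_offset / 2
    x2off[idxF1] <- seq(tilt_offset / 2, -tilt_offset / 2,
                        length.out = n_fb1)
    x2off[idxR] <- -tilt_offset / 2
    x2off[idxF2] <- seq(-tilt_offset / 2, tilt_offset / 2,
                        length.out = n_fb2)
    lines[[2 * i - 1]] <- data.frame(view = "L", start = idxL[1],
                                     end = idxL[n_line])
    lines[[2 * i]] <- data.frame(view = "R", start = idxR[1],
                                 end = idxR[n_line])
  }
  structure(list(sample_rate = sample_rate,
                 t = (seq_len(n_tot) - 1) / sample_rate,
                 X1 = x1, X2 = x1 + x2off, Y1 = y, Y2 = y,
                 lines = do.call(rbind, lines),
                 tilt_offset = tilt_offset,
                 duration = n_tot / sample_rate),
            class = "scan_waveforms")
}

#' Export waveforms as CSV
#'
#' One row per sample: time and the four mirror signals.
#'
#' @param wf A [build_waveforms()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(wf, path) {
  utils::write.csv(data.frame(t = wf$t, X1 = wf$X1, X2 = wf$X2,
                              Y1 = wf$Y1, Y2 = wf$Y2),
                   path, row.names = FALSE)
  invisible(path)
}
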