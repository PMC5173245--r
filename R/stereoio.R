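# Conversion of raw interlaced scan frames into display-ready stereo pairs
# and stereo export formats (side-by-side, red/cyan anaglyph).

#' Deinterlace a raw frame into a stereo pair
#'
#' Odd rows (1-based) of the raw `2M x N` frame are the left-view lines,
#' even rows the right-view lines; each deinterlaced `M x N` matrix is then
#' rotated 90 degrees (counter-clockwise by default) so the disparity axis
#' is horizontal, giving `N x M` views.  Pixel values are moved, never
#' interpolated.
#'
#' @param raw A `raw_frame` (see [interlace_views()]) or a plain matrix with
#'   an even number of rows.
#' @param parallax_alpha,pixel_size Stereo geometry recorded in the pair
#'   (defaulted from the raw frame's geometry when available).
#' @param rows_order `"left-first"` (odd rows are the left view, default) or
#'   `"right-first"`.
#' @param rotate Rotation direction, `"ccw"` (default) or `"cw"`.
#' @return Object of class `stereo_pair`: `left`, `right` (`N x M`),
#'   `parallax_alpha`, `pixel_size`.
#' @export
deinterlace <- function(raw, parallax_alpha = 2.5, pixel_size = 130 / 512,
                        rows_order = c("left-first", "right-first"),
                        rotate = c("ccw", "cw")) {
  rows_order <- match.arg(rows_order)
  rotate <- match.arg(rotate)
  if (inherits(raw, "raw_frame")) {
    pixel_size <- raw$frame$pixel_size
    raw <- raw$values
  }
  if (nrow(raw) %% 2 != 0) stop("raw frame must have an even row count")
  odd <- raw[seq(1, nrow(raw), by = 2), , drop = FALSE]
  even <- raw[seq(2, nrow(raw), by = 2), , drop = FALSE]
  if (rows_order == "right-first") { tmp <- odd; odd <- even; even <- tmp }
  rot <- if (rotate == "ccw") rot90ccw else rot90cw
  structure(list(left = rot(odd), right = rot(even),
                 parallax_alpha = parallax_alpha, pixel_size = pixel_size),
            class = "stereo_pair")
}

#' Construct a stereo pair from two view images
#'
#' @param left,right Same-shaped nonnegative matrices.
#' @param parallax_alpha Full parallax angle in degrees.
#' @param pixel_size Pixel pitch in um.
#' @return A `stereo_pair`.
#' @export
stereo_pair <- function(left, right, parallax_alpha = 2.5,
                        pixel_size = 130 / 512) {
  if (!identical(dim(left), dim(right))) stop("left/right shape mismatch")
  structure(list(left = left, right = right,
                 parallax_alpha = parallax_alpha, pixel_size = pixel_size),
            class = "stereo_pair")
}

# percentile contrast stretch to [0, 1]
stretch01 <- function(img, lo = 0.001, hi = 0.999) {
  q <- stats::quantile(img, c(lo, hi), names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(img), ncol(img)))
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Write a side-by-side stereo image
#'
#' Left and right views concatenated horizontally with a configurable gap,
#' for viewing with 3D shutter glasses / cross-eyed viewing.
#'
#' @param pair A `stereo_pair`.
#' @param path Output path; `.png` or `.tif`/`.tiff` selects the format.
#' @param gap Gap width in pixels (filled with zeros).
#' @param bits 8 or 16.
#' @param normalize Contrast-stretch both views jointly to full scale
#'   (default TRUE; set FALSE to write raw values, TIFF only).
#' @return `path`, invisibly.
#' @export
write_side_by_side <- function(pair, path, gap = 0, bits = 8,
                               normalize = TRUE) {
  img <- cbind(pair$left, matrix(0, nrow(pair$left), gap), pair$right)
  fmt <- tolower(tools::file_ext(path))
  if (normalize) {
    mx <- max(img)
    img <- if (mx > 0) img / mx else img
    img <- round(img * (2^bits - 1))
  }
  if (fmt == "png") write_png(img, path, bits = bits)
  else write_tiff(img, path, bits = bits)
  invisible(path)
}

#' Write a red/cyan anaglyph
#'
#' Left view in the red channel, right view in green and blue (cyan); each
#' channel is independently contrast-normalised with a 0.1-99.9 percentile
#' stretch before 8-bit quantisation.
#'
#' @param pair A `stereo_pair`.
#' @param path Output path; `.png` (default behaviour) or `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
write_anaglyph <- function(pair, path) {
  l <- round(stretch01(pair$left) * 255)
  r <- round(stretch01(pair$right) * 255)
  rgbimg <- array(0, c(nrow(l), ncol(l), 3))
  rgbimg[, , 1] <- l
  rgbimg[, , 2] <- r
  rgbimg[, , 3] <- r
  fmt <- tolower(tools::file_ext(path))
  if (fmt %in% c("tif", "tiff")) write_tiff(rgbimg, path, bits = 8, rgb = TRUE)
  else write_png(rgbimg, path)
  invisible(path)
}

#' Anaglyph as an in-memory array
#'
#' Same channel mapping and per-channel normalisation as [write_anaglyph()],
#' returned as a `rows x cols x 3` array in [0, 255].
#'
#' @param pair A `stereo_pair`.
#' @return Numeric array.
#' @export
anaglyph_array <- function(pair) {
  l <- round(stretch01(pair$left) * 255)
  r <- round(stretch01(pair$right) * 255)
  out <- array(0, c(nrow(l), ncol(l), 3))
  out[, , 1] <- l; out[, , 2] <- r; out[, , 3] <- r
  out
}
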