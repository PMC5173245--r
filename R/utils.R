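# Shared array / FFT helpers.  All physical lengths in this package are in
# micrometres (um) and angles in degrees unless a function says otherwise.

#' Rotate a matrix by 90 degrees
#'
#' `rot90ccw()` rotates counter-clockwise, `rot90cw()` clockwise; the two are
#' exact inverses.  Used to move between scan space (rows = slow-axis lines)
#' and display space (disparity axis horizontal).
#'
#' @param a A matrix.
#' @return The rotated matrix.
#' @export
rot90ccw <- function(a) {
  stopifnot(is.matrix(a))
  t(a)[ncol(a):1, , drop = FALSE]
}

#' @rdname rot90ccw
#' @export
rot90cw <- function(a) {
  stopifnot(is.matrix(a))
  t(a[nrow(a):1, , drop = FALSE])
}

# fftshift/ifftshift for matrices (centre sample at index floor(n/2)+1).
fftshift2 <- function(a) {
  n1 <- nrow(a); n2 <- ncol(a)
  a[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2)), drop = FALSE]
}

ifftshift2 <- function(a) {
  n1 <- nrow(a); n2 <- ncol(a)
  a[c((ceiling(n1 / 2) + 1):n1, 1:ceiling(n1 / 2)),
    c((ceiling(n2 / 2) + 1):n2, 1:ceiling(n2 / 2)), drop = FALSE]
}

# FFT frequency axis in cycles per sample, fftshift'd to ascending order
# only when shift = TRUE; default matches R's fft() ordering.
fft_freq <- function(n, shift = FALSE) {
  f <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L)) / n
  if (shift) sort(f) else f
}

#' 2D convolution via FFT
#'
#' Circular (periodic-boundary) convolution of an image with a kernel whose
#' centre is at `(floor(nrow/2)+1, floor(ncol/2)+1)`.  Output has the same
#' shape as `image`.  The kernel must not be larger than the image.
#'
#' @param image Numeric matrix.
#' @param kernel Numeric matrix (odd dimensions recommended).
#' @return Numeric matrix, same shape as `image`.
#' @export
conv2_fft <- function(image, kernel) {
  if (nrow(kernel) > nrow(image) || ncol(kernel) > ncol(image)) {
    stop("kernel is larger than the image")
  }
  kp <- matrix(0, nrow(image), ncol(image))
  kr <- nrow(kernel); kc <- ncol(kernel)
  kp[1:kr, 1:kc] <- kernel
  # shift kernel centre to (1,1) so convolution does not translate the image
  cr <- floor(kr / 2); cc <- floor(kc / 2)
  kp <- kp[c((cr + 1):nrow(kp), seq_len(cr)), c((cc + 1):ncol(kp), seq_len(cc)),
           drop = FALSE]
  re <- Re(stats::fft(stats::fft(image) * stats::fft(kp), inverse = TRUE)) /
    length(image)
  re
}

# Isotropic 2D Gaussian kernel, sum-normalised.
gaussian_kernel2 <- function(sigma, half_width = ceiling(3 * sigma)) {
  x <- seq(-half_width, half_width)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Linear interpolation of the x where y crosses `level` between samples i,i+1.
interp_crossing <- function(x, y, i, level) {
  x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
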