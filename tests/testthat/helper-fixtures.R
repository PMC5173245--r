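# Shared small-scale fixtures.  Frames are deliberately small (128-256 px)
# so the default suite stays fast; full-scale runs live in the acceptance
# tests.

small_frame <- function(n = 128L) frame_geometry(n, n, 130 / 512)

default_geom <- function(pixel_size = 130 / 512) {
  stereo_geometry(parallax_alpha = 2.5, dx = 0.77, pixel_size = pixel_size)
}

# kernel is moderately expensive; compute once per session
.kern_cache <- new.env(parent = emptyenv())
test_kernel <- function(pixel_size = 130 / 512) {
  key <- as.character(pixel_size)
  if (is.null(.kern_cache[[key]])) {
    .kern_cache[[key]] <- bessel_psf_kernel(pixel_size)
  }
  .kern_cache[[key]]
}

# phantom with explicit bead table (bypasses random placement)
manual_phantom <- function(beads, extent = c(32, 32, 40)) {
  ph <- make_phantom(0, extent = extent)
  beads$id <- seq_len(nrow(beads))
  if (is.null(beads$brightness)) beads$brightness <- 1
  ph$beads <- beads
  ph
}

# centre of mass of an image (in pixel units, col = x, row = y)
centre_of_mass <- function(img) {
  w <- img / sum(img)
  c(x = sum(w * col(img)), y = sum(w * row(img)))
}

render_scene <- function(beads, frame = small_frame(),
                         geom = default_geom(), extent = c(32, 32, 40)) {
  ph <- manual_phantom(beads, extent)
  k <- test_kernel(frame$pixel_size)
  list(phantom = ph,
       left = render_view(ph, "left", geom, frame, k),
       right = render_view(ph, "right", geom, frame, k),
       frame = frame, geom = geom, kernel = k)
}
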