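# Minimal baseline TIFF and PNG writers/readers.  No TIFF/PNG package is
# available in the target environment, so the package carries its own
# implementation of the small subset it needs: uncompressed little-endian
# baseline TIFF (grayscale 8/16-bit unsigned or 32-bit float, optional RGB,
# multi-page, single strip per page) and PNG (8/16-bit gray, 8-bit RGB,
# zlib via memCompress, filter type 0).
#
# Image matrices are oriented rows = image rows (top first), columns = image
# columns (left first).

tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)

#' Write a (multi-page) TIFF
#'
#' @param images A matrix, a 3D array (`rows x cols x pages`, or
#'   `rows x cols x 3` with `rgb = TRUE` for a single RGB page), or a list of
#'   matrices / `rows x cols x 3` arrays.
#' @param path Output path.
#' @param bits Bits per sample: 8, 16 (unsigned) or 32 (float).
#' @param sample_format `"uint"` or `"float"` (float implies `bits = 32`).
#' @param rgb Interpret a `rows x cols x 3` array as one RGB page.
#' @param description Optional character string stored as ImageDescription.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(images, path, bits = 16,
                       sample_format = c("uint", "float"), rgb = FALSE,
                       description = NULL) {
  sample_format <- match.arg(sample_format)
  if (sample_format == "float") bits <- 32
  if (!bits %in% c(8, 16, 32)) stop("bits must be 8, 16 or 32")
  pages <- normalize_pages(images, rgb)
  con <- file(path, "wb")
  on.exit(close(con))
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  offset <- 8L
  for (p in seq_along(pages)) {
    img <- pages[[p]]
    spp <- if (length(dim(img)) == 3) 3L else 1L
    h <- dim(img)[1]; wd <- dim(img)[2]
    desc_raw <- if (!is.null(description) && p == 1) {
      c(charToRaw(description), as.raw(0))
    } else NULL
    n_entries <- 10L + !is.null(desc_raw)
    ifd_size <- 2L + 12L * n_entries + 4L
    bps_extra <- if (spp == 3L) 6L else 0L            # BitsPerSample array
    desc_size <- if (!is.null(desc_raw) && length(desc_raw) > 4)
      length(desc_raw) else 0L
    data_off <- offset + ifd_size + bps_extra + desc_size
    strip_bytes <- h * wd * spp * (bits / 8)
    next_ifd <- if (p < length(pages)) data_off + strip_bytes else 0L
    # interleave samples, row-major scanlines
    if (spp == 3L) {
      px <- aperm(img, c(3, 2, 1))                    # sample, col, row
    } else {
      px <- t(img)                                    # col, row
    }
    vals <- as.vector(px)

    entry <- function(tag, type, count, value) {
      w2(tag); w2(tiff_types[[type]]); w4(count)
      if (type == "SHORT" && count == 1) { w2(value); w2(0L) } else w4(value)
    }
    w2(n_entries)
    entry(256L, "LONG", 1L, wd)                        # ImageWidth
    entry(257L, "LONG", 1L, h)                         # ImageLength
    if (spp == 3L) {
      entry(258L, "SHORT", 3L, offset + ifd_size)      # BitsPerSample (ptr)
    } else {
      entry(258L, "SHORT", 1L, bits)
    }
    entry(259L, "SHORT", 1L, 1L)                       # no compression
    entry(262L, "SHORT", 1L, if (spp == 3L) 2L else 1L)  # photometric
    if (!is.null(desc_raw)) {
      if (length(desc_raw) <= 4) {
        w2(270L); w2(tiff_types[["ASCII"]]); w4(length(desc_raw))
        pad <- c(desc_raw, raw(4 - length(desc_raw)))
        writeBin(pad, con)
      } else {
        entry(270L, "ASCII", length(desc_raw), offset + ifd_size + bps_extra)
      }
    }
    entry(273L, "LONG", 1L, data_off)                  # StripOffsets
    entry(277L, "SHORT", 1L, spp)                      # SamplesPerPixel
    entry(278L, "LONG", 1L, h)                         # RowsPerStrip
    entry(279L, "LONG", 1L, strip_bytes)               # StripByteCounts
    entry(339L, "SHORT", 1L,
          if (sample_format == "float") 3L else 1L)    # SampleFormat
    w4(next_ifd)
    if (spp == 3L) { w2(bits); w2(bits); w2(bits) }
    if (desc_size > 0) writeBin(desc_raw, con)
    if (sample_format == "float") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else if (bits == 16) {
      v <- as.integer(round(pmin(pmax(vals, 0), 65535)))
      # writeBin size=2 rejects values > 32767; write as raw pairs
      writeBin(as.raw(rbind(v %% 256L, v %/% 256L)), con)
    } else {
      writeBin(as.raw(as.integer(round(pmin(pmax(vals, 0), 255)))), con)
    }
    offset <- data_off + strip_bytes
  }
  invisible(path)
}

normalize_pages <- function(images, rgb) {
  if (is.list(images)) return(images)
  if (is.matrix(images)) return(list(images))
  if (length(dim(images)) == 3) {
    if (rgb) {
      stopifnot(dim(images)[3] == 3)
      return(list(images))
    }
    return(lapply(seq_len(dim(images)[3]), function(k) images[, , k]))
  }
  stop("images must be a matrix, 3D array, or list of matrices")
}

#' Read a TIFF written by this package (baseline, uncompressed)
#'
#' @param path TIFF path.
#' @return A list of pages; each grayscale page a numeric matrix, each RGB
#'   page a `rows x cols x 3` array.  The first page's ImageDescription, if
#'   present, is attached as attribute `description`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!(raw[1] == charToRaw("I") && raw[2] == charToRaw("I"))) {
    stop("only little-endian TIFF supported")
  }
  u16 <- function(o) as.integer(raw[o + 1]) + 256L * as.integer(raw[o + 2])
  u32 <- function(o) as.integer(raw[o + 1]) + 256 * as.integer(raw[o + 2]) +
    65536 * as.integer(raw[o + 3]) + 16777216 * as.integer(raw[o + 4])
  ifd_off <- u32(4)
  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n <- u16(ifd_off)
    tags <- list()
    for (i in seq_len(n)) {
      eo <- ifd_off + 2 + 12 * (i - 1)
      tag <- u16(eo); type <- u16(eo + 2); count <- u32(eo + 4)
      val <- if (type == tiff_types[["SHORT"]] && count == 1) u16(eo + 8)
             else u32(eo + 8)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        value = val, value_offset = eo + 8)
    }
    g <- function(tag, default = NULL) {
      t <- tags[[as.character(tag)]]
      if (is.null(t)) default else t$value
    }
    if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
    wd <- g(256); h <- g(257); spp <- g(277, 1L)
    sf <- g(339, 1L)
    bits <- {
      t <- tags[["258"]]
      if (is.null(t)) 1L
      else if (t$count == 1) t$value
      else u16(t$value)                    # array: read first entry
    }
    dtag <- tags[["270"]]
    if (!is.null(dtag) && is.null(description)) {
      o <- if (dtag$count <= 4) dtag$value_offset else dtag$value
      description <- rawToChar(raw[(o + 1):(o + dtag$count - 1)])
    }
    # strips
    st <- tags[["273"]]; sc <- tags[["279"]]
    n_strips <- st$count
    offs <- if (n_strips == 1) st$value else
      vapply(seq_len(n_strips) - 1L, function(k) u32(st$value + 4 * k), 0)
    cnts <- if (n_strips == 1) sc$value else
      vapply(seq_len(n_strips) - 1L, function(k) u32(sc$value + 4 * k), 0)
    bytes <- unlist(lapply(seq_len(n_strips), function(k) {
      raw[(offs[k] + 1):(offs[k] + cnts[k])]
    }))
    npx <- h * wd * spp
    vals <- if (sf == 3L) {
      readBin(bytes, "numeric", n = npx, size = 4, endian = "little")
    } else if (bits == 16) {
      m <- matrix(as.integer(bytes), nrow = 2)
      m[1, ] + 256L * m[2, ]
    } else {
      as.integer(bytes)
    }
    page <- if (spp == 3L) {
      aperm(array(vals, c(3, wd, h)), c(3, 2, 1))
    } else {
      t(matrix(vals, wd, h))
    }
    pages[[length(pages) + 1]] <- page
    ifd_off <- u32(ifd_off + 2 + 12 * n)
  }
  if (!is.null(description)) attr(pages, "description") <- description
  pages
}

# ---- PNG ---------------------------------------------------------------

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L) {
            bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320 as signed
          } else bitwShiftR(c, 1)
        }
        t[i + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

# R's bitwShiftR is a logical shift on the 32-bit pattern, which is exactly
# what the reflected CRC-32 update needs.
crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  v <- as.integer(bytes)
  for (b in v) {
    idx <- bitwAnd(bitwXor(c, b), 255L)
    c <- bitwXor(bitwShiftR(c, 8), tab[idx + 1])
  }
  bitwXor(c, -1L)
}

int_to_raw4 <- function(x) {
  # big-endian unsigned 32-bit from a (possibly negative) R integer
  xr <- as.raw(c(bitwAnd(bitwShiftR(x, 24), 255L),
                 bitwAnd(bitwShiftR(x, 16), 255L),
                 bitwAnd(bitwShiftR(x, 8), 255L),
                 bitwAnd(x, 255L)))
  xr
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(int_to_raw4(length(data)), body, int_to_raw4(crc32(body)))
}

#' Write a PNG image
#'
#' Supports 8/16-bit grayscale matrices and 8-bit RGB `rows x cols x 3`
#' arrays.  Values must already be integers in range ([0,255] or [0,65535]).
#'
#' @param image Matrix (gray) or `rows x cols x 3` array (RGB).
#' @param path Output path.
#' @param bits 8 or 16 (grayscale only; RGB is always 8).
#' @return `path`, invisibly.
#' @export
write_png <- function(image, path, bits = 8) {
  rgb <- length(dim(image)) == 3
  if (rgb) bits <- 8
  h <- dim(image)[1]; w <- dim(image)[2]
  if (rgb) {
    px <- aperm(image, c(3, 2, 1))          # channel, col, row
    v <- as.integer(as.vector(px))
    scan <- matrix(as.raw(v), nrow = 3 * w)
  } else {
    v <- as.integer(t(image))               # row-major
    if (bits == 16) {
      scan <- matrix(as.raw(rbind(v %/% 256L, v %% 256L)), nrow = 2 * w)
    } else {
      scan <- matrix(as.raw(v), nrow = w)
    }
  }
  # prepend filter byte 0 to each scanline
  rawdat <- as.raw(rbind(raw(1), scan))
  comp <- memCompress(rawdat, "gzip")       # zlib stream in R
  ihdr <- c(int_to_raw4(w), int_to_raw4(h), as.raw(bits),
            as.raw(if (rgb) 2L else 0L), raw(3))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", comp),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write a raw interlaced frame (and read one back)
#'
#' Raw frames are stored as 16-bit multi-page TIFF with the frame geometry
#' in the ImageDescription as JSON.
#'
#' @param raw_frames A `raw_frame` or list of them (time series).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raw_frames <- function(raw_frames, path) {
  if (inherits(raw_frames, "raw_frame")) raw_frames <- list(raw_frames)
  fr <- raw_frames[[1]]$frame
  desc <- jsonlite::toJSON(list(n_fast = fr$n_fast, m_slow = fr$m_slow,
                                pixel_size = fr$pixel_size,
                                depth_range = fr$depth_range),
                           auto_unbox = TRUE, digits = NA)
  mx <- max(vapply(raw_frames, function(r) max(r$values), 0), 1e-12)
  pages <- lapply(raw_frames, function(r) r$values / mx * 65535)
  write_tiff(pages, path, bits = 16, description = as.character(desc))
  invisible(path)
}

#' @rdname write_raw_frames
#' @param frame Optional [frame_geometry()]; defaults to the one stored in
#'   the TIFF description (error if neither is available).
#' @return `read_raw_frames()`: list of `raw_frame` objects.
#' @export
read_raw_frames <- function(path, frame = NULL) {
  pages <- read_tiff(path)
  if (is.null(frame)) {
    desc <- attr(pages, "description")
    if (is.null(desc)) stop("no frame geometry stored in ", path,
                            "; pass `frame`")
    meta <- jsonlite::fromJSON(desc)
    frame <- frame_geometry(meta$n_fast, meta$m_slow, meta$pixel_size,
                            meta$depth_range %||% 90)
  }
  lapply(pages, function(p) structure(list(values = p, frame = frame),
                                      class = "raw_frame"))
}
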