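# Minimal 3D track linking across a stereo time series: greedy
# nearest-neighbour association between consecutive frames, gated by a
# maximum displacement.  A deliberate simplification of full tracking
# suites (no gap closing, merging or motion models) — sufficient for the
# sparse bead samples this package simulates.

#' Link per-frame 3D detections into tracks
#'
#' Detections in consecutive frames are linked greedily in ascending 3D
#' distance; links longer than `max_displacement` are forbidden, and any
#' detection that receives no link starts a new track.  Unmatched
#' detections (`matched = FALSE` or `z = NA`) are ignored.
#'
#' @param per_frame_detections List of `object_depths` data frames (or any
#'   frames with `x`, `y`, `z`), one per time point.
#' @param max_displacement Gate in um.
#' @return Object of class `track_set`: data frame `tracks` with columns
#'   `track_id`, `frame`, `x`, `y`, `z`.
#' @export
link_tracks <- function(per_frame_detections, max_displacement) {
  stopifnot(max_displacement > 0)
  clean <- lapply(per_frame_detections, function(d) {
    if ("matched" %in% names(d)) d <- d[d$matched & !is.na(d$z), , drop = FALSE]
    d[!is.na(d$z), c("x", "y", "z"), drop = FALSE]
  })
  rows <- list()
  next_id <- 1L
  prev_ids <- integer()
  prev <- NULL
  for (f in seq_along(clean)) {
    cur <- clean[[f]]
    cur_ids <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev) > 0 && nrow(cur) > 0) {
      pr <- expand.grid(ip = seq_len(nrow(prev)), ic = seq_len(nrow(cur)))
      d <- sqrt((prev$x[pr$ip] - cur$x[pr$ic])^2 +
                (prev$y[pr$ip] - cur$y[pr$ic])^2 +
                (prev$z[pr$ip] - cur$z[pr$ic])^2)
      ordidx <- order(d)
      usedp <- logical(nrow(prev)); usedc <- logical(nrow(cur))
      for (k in ordidx) {
        if (d[k] > max_displacement) break
        ip <- pr$ip[k]; ic <- pr$ic[k]
        if (!usedp[ip] && !usedc[ic]) {
          usedp[ip] <- TRUE; usedc[ic] <- TRUE
          cur_ids[ic] <- prev_ids[ip]
        }
      }
    }
    for (ic in which(is.na(cur_ids))) {
      cur_ids[ic] <- next_id
      next_id <- next_id + 1L
    }
    if (nrow(cur) > 0) {
      rows[[length(rows) + 1]] <- data.frame(track_id = cur_ids, frame = f,
                                             x = cur$x, y = cur$y, z = cur$z)
    }
    prev <- cur
    prev_ids <- cur_ids
  }
  tracks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_id = integer(), frame = integer(),
               x = numeric(), y = numeric(), z = numeric())
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, max_displacement = max_displacement),
            class = "track_set")
}

#' Export tracks as CSV
#'
#' @param track_set A [link_tracks()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(track_set, path) {
  utils::write.csv(track_set$tracks, path, row.names = FALSE)
  invisible(path)
}
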