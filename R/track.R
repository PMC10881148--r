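#' Construct a single cell track
#'
#' A track is an ordered list of (frame, x, y) points with a spatial/temporal
#' calibration. Frames are 0-based and must be strictly increasing; gaps
#' (missing frames) are allowed and represent gap-closed detections.
#'
#' @param frame Integer vector of 0-based frame indices.
#' @param x,y Pixel coordinates (x = column, y = row, origin top-left,
#'   0-based pixel centres); may be subpixel.
#' @param track_id Identifier.
#' @param calibration A [calibration()] object.
#' @return An object of class `mm_track`.
#' @export
as_track <- function(frame, x, y, track_id = 1L,
                     calibration = macromigr::calibration()) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) < 2L) stop("a track needs at least 2 points", call. = FALSE)
  o <- order(frame)
  frame <- as.integer(frame[o]); x <- as.numeric(x[o]); y <- as.numeric(y[o])
  if (any(diff(frame) <= 0L)) {
    stop("track frames must be strictly increasing", call. = FALSE)
  }
  structure(
    list(track_id = track_id, frame = frame, x = x, y = y,
         calibration = as_calibration(calibration)),
    class = "mm_track"
  )
}

#' @export
print.mm_track <- function(x, ...) {
  cat(sprintf(
    "track %s: %d points, frames %d-%d\n",
    format(x$track_id), length(x$frame), min(x$frame), max(x$frame)
  ))
  invisible(x)
}

# Path length in calibrated units (straight-line across gaps).
track_path_length <- function(track) {
  mpp <- track$calibration$microns_per_pixel
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2)) * mpp
}

# Net start-to-end displacement in calibrated units.
track_net_displacement <- function(track) {
  n <- length(track$x)
  mpp <- track$calibration$microns_per_pixel
  sqrt((track$x[n] - track$x[1])^2 + (track$y[n] - track$y[1])^2) * mpp
}

# Frames spanned, including gap frames.
track_duration_frames <- function(track) {
  diff(range(track$frame)) + 1L
}

#' Convert between track lists and tidy tables
#'
#' @param tracks A list of `mm_track` objects.
#' @return `tracks_to_table()`: a tibble with columns
#'   `track_id, frame, x, y`. `table_to_tracks()`: a list of `mm_track`.
#' @export
tracks_to_table <- function(tracks) {
  if (length(tracks) == 0) {
    return(tibble::tibble(track_id = integer(), frame = integer(),
                          x = numeric(), y = numeric()))
  }
  do.call(rbind, lapply(tracks, function(t) {
    tibble::tibble(track_id = t$track_id, frame = t$frame, x = t$x, y = t$y)
  }))
}

#' @rdname tracks_to_table
#' @param tab A data frame with columns `track_id, frame, x, y`.
#' @param calibration A [calibration()] applied to every track.
#' @export
table_to_tracks <- function(tab, calibration = macromigr::calibration()) {
  need <- c("track_id", "frame", "x", "y")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("track table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname(lapply(split(tab, tab$track_id), function(g) {
    as_track(g$frame, g$x, g$y, track_id = g$track_id[1],
             calibration = calibration)
  }))
}

#' Read and write track tables as CSV
#'
#' The schema is `track_id, frame, x, y` with a mandatory header; extra
#' columns (as in TrackMate-dialect exports) are ignored on read. The round
#' trip is lossless to 6 decimal places.
#'
#' @param path CSV path.
#' @param calibration A [calibration()] attached to each track on read.
#' @return `read_tracks()`: list of `mm_track`.
#' @export
read_tracks <- function(path, calibration = macromigr::calibration()) {
  tab <- read.csv(path, check.names = FALSE)
  need <- c("track_id", "frame", "x", "y")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("track CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (id in unique(tab$track_id)) {
    f <- tab$frame[tab$track_id == id]
    if (any(diff(f) <= 0)) {
      stop(sprintf("non-monotone frames in track %s", format(id)), call. = FALSE)
    }
  }
  table_to_tracks(tab[need], calibration = calibration)
}

#' @rdname read_tracks
#' @param tracks A list of `mm_track` objects.
#' @export
write_tracks <- function(tracks, path) {
  tab <- tracks_to_table(tracks)
  tab$x <- round(tab$x, 6)
  tab$y <- round(tab$y, 6)
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
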