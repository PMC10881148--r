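#' Track mean speed (velocity)
#'
#' Accumulated path length (sum of successive point-to-point distances, in
#' microns) divided by the elapsed time between the first and last frame, in
#' minutes. This is the per-track "velocity" of the chemotaxis-tool
#' convention. Gap steps contribute their straight-line distance; elapsed
#' time spans the full first-to-last interval.
#'
#' @param track An `mm_track`.
#' @return Speed in microns per minute.
#' @examples
#' t <- as_track(0:3, c(0, 1, 2, 3), c(0, 0, 0, 0), calibration = calibration(1, 10))
#' track_speed(t) # 3 um over 30 min
#' @export
track_speed <- function(track) {
  stopifnot(inherits(track, "mm_track"))
  elapsed_min <- diff(range(track$frame)) * track$calibration$minutes_per_frame
  track_path_length(track) / elapsed_min
}

#' Track persistence (directness, d/T)
#'
#' Net start-to-end displacement divided by the accumulated path length.
#' 1 means perfectly straight migration; 0 means the cell returned to its
#' starting point. Undefined (NA) for a track that never moved.
#'
#' @param track An `mm_track`.
#' @param method `"directness"` (the d/T statistic, default) or
#'   `"displacement_rate"`, net displacement in microns divided by elapsed
#'   minutes (an alternative reading of "d/T" retained for comparison; not
#'   dimensionless).
#' @return Dimensionless persistence in [0, 1] (or um/min for
#'   `"displacement_rate"`); NA if the path length is zero.
#' @examples
#' t <- as_track(0:2, c(0, 3, 3), c(0, 0, 4))
#' track_persistence(t) # 5 / 7
#' @export
track_persistence <- function(track, method = c("directness", "displacement_rate")) {
  stopifnot(inherits(track, "mm_track"))
  method <- match.arg(method)
  d <- track_net_displacement(track)
  if (method == "displacement_rate") {
    elapsed_min <- diff(range(track$frame)) * track$calibration$minutes_per_frame
    return(d / elapsed_min)
  }
  path <- track_path_length(track)
  if (path <= 0) return(NA_real_)
  min(d / path, 1)
}

#' Per-track motility metrics table
#'
#' @param tracks A list of `mm_track` objects.
#' @return A tibble with columns `track_id, n_frames, duration_min,
#'   mean_speed_um_min, net_disp_um, path_um, persistence`.
#' @export
track_metrics <- function(tracks) {
  if (length(tracks) == 0L) {
    return(tibble::tibble(
      track_id = integer(), n_frames = integer(), duration_min = numeric(),
      mean_speed_um_min = numeric(), net_disp_um = numeric(),
      path_um = numeric(), persistence = numeric()
    ))
  }
  do.call(rbind, lapply(tracks, function(t) {
    tibble::tibble(
      track_id = t$track_id,
      n_frames = length(t$frame),
      duration_min = diff(range(t$frame)) * t$calibration$minutes_per_frame,
      mean_speed_um_min = track_speed(t),
      net_disp_um = track_net_displacement(t),
      path_um = track_path_length(t),
      persistence = track_persistence(t)
    )
  }))
}
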