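#' Spatial and temporal calibration of a movie or image
#'
#' Bundles the two scale factors that convert pixel/frame quantities to
#' physical units. The default frame interval of 10 minutes matches the
#' overnight (>= 16 h) acquisition protocol the analysis settings were
#' designed for.
#'
#' @param microns_per_pixel Length of one pixel side, in microns. Must be > 0.
#' @param minutes_per_frame Time between consecutive frames, in minutes.
#'   Must be > 0.
#' @return An object of class `mm_calibration`.
#' @examples
#' cal <- calibration(0.65, 10)
#' cal$microns_per_pixel
#' @export
calibration <- function(microns_per_pixel = 1, minutes_per_frame = 10) {
  check_scalar(microns_per_pixel, "microns_per_pixel", lo = 0, lo_open = TRUE)
  check_scalar(minutes_per_frame, "minutes_per_frame", lo = 0, lo_open = TRUE)
  structure(
    list(
      microns_per_pixel = microns_per_pixel,
      minutes_per_frame = minutes_per_frame
    ),
    class = "mm_calibration"
  )
}

#' @export
print.mm_calibration <- function(x, ...) {
  cat(sprintf(
    "calibration: %g um/px, %g min/frame\n",
    x$microns_per_pixel, x$minutes_per_frame
  ))
  invisible(x)
}

as_calibration <- function(x) {
  if (inherits(x, "mm_calibration")) return(x)
  if (is.list(x) && all(c("microns_per_pixel", "minutes_per_frame") %in% names(x))) {
    return(calibration(x$microns_per_pixel, x$minutes_per_frame))
  }
  stop("cannot interpret `calibration`", call. = FALSE)
}
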