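#' Tracking configuration
#'
#' Detection and linking settings. The defaults for linking distance (70.0),
#' maximum gap (10 frames), minimum duration (20 frames), minimum mean speed
#' (2.00) and minimum displacement (8.00) are the plugin settings used in the
#' original analysis; distance/speed thresholds are in calibrated units (with
#' the default calibration of 1 um/px they coincide numerically with pixel
#' units).
#'
#' @param spot_diameter Expected spot diameter, pixels; sets the
#'   Laplacian-of-Gaussian scale.
#' @param quality_threshold Minimum detector response retained.
#' @param max_link_distance Maximum frame-to-frame (and gap-closing) link
#'   distance, calibrated units.
#' @param max_gap_frames Maximum number of missing frames a gap-closing link
#'   may bridge.
#' @param min_duration_frames Minimum frames spanned by a retained track.
#' @param min_mean_speed Minimum track mean speed, calibrated units per
#'   frame interval.
#' @param min_displacement Minimum net track displacement, calibrated units.
#' @param background_sigma Gaussian sigma for large-scale background
#'   subtraction before detection (the contrast-flattening step); `0`
#'   disables it.
#' @return An object of class `mm_tracking_config`.
#' @export
tracking_config <- function(spot_diameter = 8,
                            quality_threshold = 0.2,
                            max_link_distance = 70,
                            max_gap_frames = 10L,
                            min_duration_frames = 20L,
                            min_mean_speed = 2.00,
                            min_displacement = 8.00,
                            background_sigma = 0) {
  check_scalar(spot_diameter, "spot_diameter", lo = 1)
  check_scalar(quality_threshold, "quality_threshold", lo = 0)
  check_scalar(max_link_distance, "max_link_distance", lo = 0)
  max_gap_frames <- check_count(max_gap_frames, "max_gap_frames")
  min_duration_frames <- check_count(min_duration_frames, "min_duration_frames")
  check_scalar(min_mean_speed, "min_mean_speed", lo = 0)
  check_scalar(min_displacement, "min_displacement", lo = 0)
  check_scalar(background_sigma, "background_sigma", lo = 0)
  structure(
    list(
      spot_diameter = spot_diameter,
      quality_threshold = quality_threshold,
      max_link_distance = max_link_distance,
      max_gap_frames = max_gap_frames,
      min_duration_frames = min_duration_frames,
      min_mean_speed = min_mean_speed,
      min_displacement = min_displacement,
      background_sigma = background_sigma
    ),
    class = "mm_tracking_config"
  )
}

# Scale-normalised Laplacian-of-Gaussian kernel. Blobs of radius
# sigma * sqrt(2) give the strongest (most negative) response; we negate so
# bright blobs score positive.
log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g <- outer(-r:r, -r:r, function(a, b) {
    rr <- a^2 + b^2
    (rr / sigma^2 - 2) * exp(-rr / (2 * sigma^2))
  })
  # zero-mean so constant backgrounds give zero response
  g <- g - mean(g)
  -g / (2 * pi * sigma^2) * sigma^2
}

#' Detect labeled cells in one frame
#'
#' Laplacian-of-Gaussian blob detection at a scale matched to
#' `spot_diameter` (sigma = diameter / (2 sqrt(2))), followed by 8-neighbour
#' local-maximum extraction above `quality_threshold` and subpixel refinement
#' by a quadratic fit along each axis. Optionally subtracts a large-scale
#' Gaussian blur of the frame first to flatten uneven background.
#'
#' @param frame_image Single-channel numeric matrix.
#' @param config A [tracking_config()].
#' @return A tibble with columns `x`, `y` (0-based pixel-centre coordinates,
#'   subpixel) and `quality` (detector response at the maximum), ordered by
#'   decreasing quality.
#' @examples
#' img <- matrix(0, 64, 64)
#' img[28:36, 28:36] <- outer(dnorm(-4:4, 0, 2), dnorm(-4:4, 0, 2))
#' detect_cells(img, tracking_config(spot_diameter = 6, quality_threshold = 1e-4))
#' @export
detect_cells <- function(frame_image, config = tracking_config()) {
  if (!is.matrix(frame_image) || length(frame_image) == 0L) {
    stop("`frame_image` must be a non-empty matrix", call. = FALSE)
  }
  if (any(!is.finite(frame_image))) {
    stop("`frame_image` contains non-finite values", call. = FALSE)
  }
  img <- frame_image
  if (config$background_sigma > 0) {
    img <- img - EBImage::gblur(img, sigma = config$background_sigma)
  }
  sigma <- config$spot_diameter / (2 * sqrt(2))
  resp <- EBImage::filter2(img, log_kernel(sigma), boundary = "replicate")
  resp <- as.matrix(resp)
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3L || nc < 3L) {
    return(tibble::tibble(x = numeric(), y = numeric(), quality = numeric()))
  }
  core <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- core >= config$quality_threshold
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- resp[2:(nr - 1) + di, 2:(nc - 1) + dj]
      # strict on the lexicographically earlier neighbour to break plateaus
      is_max <- is_max & if (di < 0 || (di == 0 && dj < 0)) core > nb else core >= nb
    }
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), quality = numeric()))
  }
  ii <- hits[, 1] + 1L
  jj <- hits[, 2] + 1L
  # quadratic subpixel refinement per axis
  offset1d <- function(m, c0, p) {
    den <- m - 2 * c0 + p
    ifelse(abs(den) > 1e-12, pmin(pmax(0.5 * (m - p) / den, -0.5), 0.5), 0)
  }
  oy <- offset1d(resp[cbind(ii - 1L, jj)], resp[cbind(ii, jj)], resp[cbind(ii + 1L, jj)])
  ox <- offset1d(resp[cbind(ii, jj - 1L)], resp[cbind(ii, jj)], resp[cbind(ii, jj + 1L)])
  out <- tibble::tibble(
    x = jj - 1 + ox,
    y = ii - 1 + oy,
    quality = resp[cbind(ii, jj)]
  )
  out[order(-out$quality), ]
}

#' Detect cells in every frame of a movie
#'
#' @param stack Numeric array `[rows, cols, frames]`.
#' @param config A [tracking_config()].
#' @return A tibble with columns `frame` (0-based), `x`, `y`, `quality`.
#' @export
detect_movie <- function(stack, config = tracking_config()) {
  stopifnot(length(dim(stack)) == 3L)
  out <- lapply(seq_len(dim(stack)[3]), function(k) {
    d <- detect_cells(stack[, , k], config)
    if (nrow(d)) d$frame <- k - 1L else d$frame <- integer(0)
    d
  })
  d <- do.call(rbind, out)
  d[c("frame", "x", "y", "quality")]
}

#' Link detections into tracks (LAP with gap closing)
#'
#' Two-pass linking in the LAP-tracker style. Pass 1 links detections in
#' consecutive frames by minimum total squared distance, forbidding links
#' longer than `max_link_distance` (calibrated units). Pass 2 closes gaps: it
#' matches ends of the pass-1 segments to later segment starts within
#' `max_link_distance` and at most `max_gap_frames` missing frames, again by
#' optimal assignment, and splices the matched segments. Unmatched
#' detections start new tracks. Both passes use an exact assignment solver;
#' equal-cost solutions are resolved deterministically by input order.
#'
#' @param detections A data frame with columns `frame` (0-based consecutive),
#'   `x`, `y` (pixels).
#' @param config A [tracking_config()].
#' @param calibration A [calibration()]; link distances are compared in
#'   calibrated units.
#' @param keep_singletons Keep unlinked single detections as one-point track
#'   stubs (plain lists, not `mm_track`)? Default drops them.
#' @return A list of [as_track()] objects (plus one-point stubs when
#'   `keep_singletons = TRUE`).
#' @export
link_tracks <- function(detections, config = tracking_config(),
                        calibration = macromigr::calibration(),
                        keep_singletons = FALSE) {
  calibration <- as_calibration(calibration)
  mpp <- calibration$microns_per_pixel
  if (is.null(detections) || nrow(detections) == 0L) return(list())
  stopifnot(all(c("frame", "x", "y") %in% names(detections)))
  det <- as.data.frame(detections)[c("frame", "x", "y")]
  det <- det[order(det$frame), ]
  maxd <- config$max_link_distance
  b <- maxd^2

  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)

  # pass 1: frame-to-frame segments (lists of detection row indices)
  segments <- list()
  head_of <- integer(0)   # segment index whose last detection is in the current frame
  prev_frame <- NULL
  for (f in frames) {
    rows <- by_frame[[as.character(f)]]
    if (is.null(prev_frame) || f != prev_frame + 1L || length(head_of) == 0L) {
      new_heads <- integer(0)
      for (r in rows) {
        segments[[length(segments) + 1L]] <- r
        new_heads <- c(new_heads, length(segments))
      }
      head_of <- new_heads
    } else {
      hx <- vapply(head_of, function(s) det$x[tail(segments[[s]], 1L)], 0)
      hy <- vapply(head_of, function(s) det$y[tail(segments[[s]], 1L)], 0)
      dx <- outer(hx, det$x[rows], "-") * mpp
      dy <- outer(hy, det$y[rows], "-") * mpp
      cost <- dx^2 + dy^2
      cost[sqrt(cost) > maxd] <- Inf
      match <- lap_match(cost, b)
      new_heads <- integer(0)
      for (k in seq_along(rows)) {
        j <- which(match == k)
        if (length(j) == 1L) {
          s <- head_of[j]
          segments[[s]] <- c(segments[[s]], rows[k])
          new_heads <- c(new_heads, s)
        } else {
          segments[[length(segments) + 1L]] <- rows[k]
          new_heads <- c(new_heads, length(segments))
        }
      }
      head_of <- new_heads
    }
    prev_frame <- f
  }

  # pass 2: gap closing between segment ends and segment starts
  ns <- length(segments)
  if (ns > 1L && config$max_gap_frames > 0L) {
    end_rows <- vapply(segments, function(s) tail(s, 1L), 0L)
    start_rows <- vapply(segments, function(s) s[1L], 0L)
    ef <- det$frame[end_rows]; sf <- det$frame[start_rows]
    cost <- matrix(Inf, ns, ns)
    for (i in seq_len(ns)) {
      gap <- sf - ef[i] - 1L  # missing frames bridged
      ok <- which(gap >= 1L & gap <= config$max_gap_frames)
      ok <- setdiff(ok, i)
      if (length(ok)) {
        d2 <- ((det$x[start_rows[ok]] - det$x[end_rows[i]])^2 +
                 (det$y[start_rows[ok]] - det$y[end_rows[i]])^2) * mpp^2
        d2[sqrt(d2) > maxd] <- Inf
        cost[i, ok] <- d2
      }
    }
    succ <- lap_match(cost, b)
    # splice chains end -> start
    has_pred <- rep(FALSE, ns)
    has_pred[succ[!is.na(succ)]] <- TRUE
    merged <- vector("list", 0)
    for (i in seq_len(ns)) {
      if (has_pred[i]) next
      chain <- segments[[i]]
      j <- succ[i]
      while (!is.na(j)) {
        chain <- c(chain, segments[[j]])
        j <- succ[j]
      }
      merged[[length(merged) + 1L]] <- chain
    }
    segments <- merged
  }

  if (!keep_singletons) segments <- Filter(function(s) length(s) >= 2L, segments)
  out <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    out[[i]] <- if (length(s) >= 2L) {
      as_track(det$frame[s], det$x[s], det$y[s],
               track_id = i, calibration = calibration)
    } else {
      list(track_id = i, frame = det$frame[s], x = det$x[s], y = det$y[s],
           calibration = calibration)
    }
  }
  out
}

#' Filter tracks on duration, mean speed, and displacement
#'
#' Retains exactly the tracks with duration >= `min_duration_frames` (frames
#' spanned, gaps included), mean speed >= `min_mean_speed` (path length in
#' calibrated units divided by elapsed frame intervals, gap steps measured
#' end-to-end) and net displacement >= `min_displacement` (calibrated units).
#' All comparisons are inclusive; input order is preserved. These filters
#' remove dead cells and artifacts, which typically have speed and
#' displacement near zero.
#'
#' @param tracks A list of `mm_track` objects.
#' @param config A [tracking_config()].
#' @return The retained subset, in input order.
#' @export
filter_tracks <- function(tracks, config = tracking_config()) {
  keep <- vapply(tracks, function(t) {
    dur <- track_duration_frames(t)
    elapsed <- diff(range(t$frame))
    speed <- track_path_length(t) / elapsed
    disp <- track_net_displacement(t)
    dur >= config$min_duration_frames &&
      speed >= config$min_mean_speed &&
      disp >= config$min_displacement
  }, logical(1))
  tracks[keep]
}
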