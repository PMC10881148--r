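#' Migration-mode parameters for the synthetic cell walker
#'
#' A cell in the simulator performs a persistent random walk: its heading
#' receives a Gaussian increment of standard deviation `angular_sd` each
#' frame and it advances by a fixed step of `mean_step_speed` times the frame
#' interval. Circularity fluctuates around `circ_baseline`; slingshot recoils
#' occur as a Bernoulli process at `slingshot_rate` events per hour, each
#' dropping circularity by `slingshot_delta_c` for one frame (followed by a
#' gradual recovery) and replacing the next step with a long
#' `slingshot_step` displacement.
#'
#' Numeric defaults of the two presets are artifact choices that reproduce
#' the qualitative contrast between adhesion-driven persistent migration
#' (fibronectin-like) and fast amoeboid meandering with recoils
#' (laminin-like); they are not measured values.
#'
#' @param mean_step_speed Mean cell speed, microns per minute.
#' @param angular_sd Per-frame heading noise, radians.
#' @param circ_baseline Baseline circularity, in (0, 1].
#' @param circ_noise_sd Per-frame circularity noise (dimensionless).
#' @param slingshot_rate Slingshot events per cell per hour.
#' @param slingshot_step Recoil displacement covered in one frame, microns.
#' @param slingshot_delta_c Circularity drop during an event, in [0, 1].
#' @param recovery_frames Frames over which circularity ramps back to
#'   baseline after an event. The ramp guarantees that one event produces
#'   exactly one supra-threshold frame-to-frame change, so a single recoil is
#'   counted once downstream.
#' @return An object of class `mm_mode_params`.
#' @seealso [fn_mode()], [lam_mode()], [simulate_tracks()]
#' @export
mode_params <- function(mean_step_speed,
                        angular_sd,
                        circ_baseline,
                        circ_noise_sd = 0.03,
                        slingshot_rate = 0,
                        slingshot_step = 0,
                        slingshot_delta_c = 0,
                        recovery_frames = 4L) {
  check_scalar(mean_step_speed, "mean_step_speed", lo = 0)
  check_scalar(angular_sd, "angular_sd", lo = 0)
  check_scalar(circ_baseline, "circ_baseline", lo = 0, hi = 1, lo_open = TRUE)
  check_scalar(circ_noise_sd, "circ_noise_sd", lo = 0)
  check_scalar(slingshot_rate, "slingshot_rate", lo = 0)
  check_scalar(slingshot_step, "slingshot_step", lo = 0)
  check_scalar(slingshot_delta_c, "slingshot_delta_c", lo = 0, hi = 1)
  recovery_frames <- check_count(recovery_frames, "recovery_frames", min = 1L)
  if (slingshot_rate > 0 && circ_baseline - slingshot_delta_c < 0) {
    stop("circ_baseline - slingshot_delta_c must be >= 0 when slingshot_rate > 0",
         call. = FALSE)
  }
  structure(
    list(
      mean_step_speed = mean_step_speed,
      angular_sd = angular_sd,
      circ_baseline = circ_baseline,
      circ_noise_sd = circ_noise_sd,
      slingshot_rate = slingshot_rate,
      slingshot_step = slingshot_step,
      slingshot_delta_c = slingshot_delta_c,
      recovery_frames = recovery_frames
    ),
    class = "mm_mode_params"
  )
}

#' @rdname mode_params
#' @export
fn_mode <- function() {
  mode_params(
    mean_step_speed = 0.35, angular_sd = 0.35,
    circ_baseline = 0.45, circ_noise_sd = 0.03,
    slingshot_rate = 0, slingshot_step = 0, slingshot_delta_c = 0
  )
}

#' @rdname mode_params
#' @export
lam_mode <- function() {
  mode_params(
    mean_step_speed = 1.05, angular_sd = 1.4,
    circ_baseline = 0.80, circ_noise_sd = 0.03,
    slingshot_rate = 0.6, slingshot_step = 20, slingshot_delta_c = 0.55
  )
}

#' Full parameter set for one simulated movie
#'
#' @param n_cells Number of cells.
#' @param n_frames Number of frames (>= 2). The default 97 corresponds to a
#'   16-hour movie at 10-minute intervals.
#' @param field_size Field dimensions `c(width, height)` in pixels.
#' @param calibration A [calibration()] object.
#' @param mode A [mode_params()] object.
#' @param detection_dropout_prob Probability that a cell is invisible in a
#'   rendered frame, in [0, 1).
#' @param seed Integer RNG seed; identical parameters and seed give
#'   bit-identical output.
#' @param start_positions Optional `n_cells x 2` matrix of starting pixel
#'   positions (x, y, 0-based pixel centres); defaults to uniform placement
#'   within the field margin.
#' @param boundary_pad_px Margin kept between cells and the field edge;
#'   positions reflect at this boundary.
#' @return An object of class `mm_sim_params`.
#' @export
sim_params <- function(n_cells,
                       n_frames = 97L,
                       field_size = c(512L, 512L),
                       calibration = macromigr::calibration(),
                       mode = fn_mode(),
                       detection_dropout_prob = 0,
                       seed = 1L,
                       start_positions = NULL,
                       boundary_pad_px = 12) {
  n_cells <- check_count(n_cells, "n_cells", min = 0L)
  n_frames <- check_count(n_frames, "n_frames", min = 2L)
  stopifnot(length(field_size) == 2L, all(field_size >= 1))
  check_scalar(detection_dropout_prob, "detection_dropout_prob",
               lo = 0, hi = 1, hi_open = TRUE)
  seed <- check_count(seed, "seed")
  calibration <- as_calibration(calibration)
  if (!inherits(mode, "mm_mode_params")) stop("`mode` must be mode_params()")
  if (!is.null(start_positions)) {
    start_positions <- as.matrix(start_positions)
    stopifnot(nrow(start_positions) == n_cells, ncol(start_positions) == 2L)
  }
  check_scalar(boundary_pad_px, "boundary_pad_px", lo = 0)
  if (2 * boundary_pad_px >= min(field_size)) {
    stop("field too small for the requested boundary pad", call. = FALSE)
  }
  structure(
    list(
      n_cells = n_cells, n_frames = n_frames,
      field_size = as.numeric(field_size),
      calibration = calibration, mode = mode,
      detection_dropout_prob = detection_dropout_prob,
      seed = seed, start_positions = start_positions,
      boundary_pad_px = boundary_pad_px
    ),
    class = "mm_sim_params"
  )
}

#' Simulate ground-truth cell tracks and shape series
#'
#' Each cell performs a persistent random walk (Gaussian heading increments,
#' fixed step length) with reflecting boundaries. Circularity is the mode
#' baseline plus Gaussian noise, clipped to (0, 1]; slingshot events are
#' drawn per frame as a Bernoulli process with probability
#' `slingshot_rate * minutes_per_frame / 60`. At an event frame the
#' circularity drops by exactly `slingshot_delta_c` relative to the previous
#' frame, then ramps back over `recovery_frames` frames in sub-threshold
#' increments, and the step leaving the event frame has length
#' `slingshot_step`. Elongation is derived from circularity as `1 / C`
#' (a round cell has elongation 1; a recoiling cell stretches).
#'
#' @param params A [sim_params()] object.
#' @return An object of class `mm_ground_truth`: a list with
#'   `data` (tibble: `track_id`, `frame`, `x_px`, `y_px`, `circularity`,
#'   `elongation`, `is_slingshot`), `slingshot_frames` (per-cell integer
#'   vectors of 0-based event frames), and `params`.
#' @examples
#' p <- sim_params(n_cells = 3, n_frames = 20, mode = lam_mode(), seed = 7)
#' truth <- simulate_tracks(p)
#' head(truth$data)
#' @export
simulate_tracks <- function(params) {
  stopifnot(inherits(params, "mm_sim_params"))
  m <- params$mode
  cal <- params$calibration
  nf <- params$n_frames
  step_px <- m$mean_step_speed * cal$minutes_per_frame / cal$microns_per_pixel
  sling_px <- m$slingshot_step / cal$microns_per_pixel
  p_event <- min(1, m$slingshot_rate * cal$minutes_per_frame / 60)
  pad <- params$boundary_pad_px
  lo <- c(pad, pad)
  hi <- params$field_size - 1 - pad

  with_seed(params$seed, {
    out <- vector("list", params$n_cells)
    sling_frames <- vector("list", params$n_cells)
    for (i in seq_len(params$n_cells)) {
      start <- if (is.null(params$start_positions)) {
        c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]))
      } else {
        params$start_positions[i, ]
      }
      theta <- runif(1, 0, 2 * pi)
      dtheta <- if (m$angular_sd > 0) rnorm(nf - 1, 0, m$angular_sd) else numeric(nf - 1)
      cnoise <- if (m$circ_noise_sd > 0) rnorm(nf, 0, m$circ_noise_sd) else numeric(nf)
      # events cannot start in the first frame or while a previous event recovers
      raw_event <- if (p_event > 0) {
        runif(nf) < p_event
      } else {
        rep(FALSE, nf)
      }
      raw_event[1] <- FALSE

      x <- numeric(nf); y <- numeric(nf)
      x[1] <- start[1]; y[1] <- start[2]
      circ <- pmin(pmax(m$circ_baseline + cnoise, 1e-6), 1)
      is_sling <- rep(FALSE, nf)
      recovering <- 0L
      for (t in seq_len(nf)) {
        if (t > 1) {
          theta <- theta + dtheta[t - 1]
          len <- if (is_sling[t - 1]) sling_px else step_px
          x[t] <- reflect_into(x[t - 1] + len * cos(theta), lo[1], hi[1])
          y[t] <- reflect_into(y[t - 1] + len * sin(theta), lo[2], hi[2])
        }
        if (recovering > 0L) {
          # linear ramp back toward baseline; each increment < delta_c
          k <- m$recovery_frames - recovering + 1L
          frac <- k / (m$recovery_frames + 1)
          circ[t] <- max(1e-6, circ[t] - (1 - frac) * m$slingshot_delta_c)
          recovering <- recovering - 1L
        } else if (raw_event[t]) {
          is_sling[t] <- TRUE
          circ[t] <- max(1e-6, circ[t - 1] - m$slingshot_delta_c)
          recovering <- m$recovery_frames
        }
      }
      out[[i]] <- tibble::tibble(
        track_id = i, frame = seq_len(nf) - 1L,
        x_px = x, y_px = y,
        circularity = circ,
        elongation = pmin(1 / circ, 8),
        is_slingshot = as.integer(is_sling)
      )
      sling_frames[[i]] <- which(is_sling) - 1L
    }
    empty <- tibble::tibble(
      track_id = integer(), frame = integer(), x_px = numeric(),
      y_px = numeric(), circularity = numeric(), elongation = numeric(),
      is_slingshot = integer()
    )
    structure(
      list(
        data = if (length(out)) do.call(rbind, out) else empty,
        slingshot_frames = sling_frames,
        params = params
      ),
      class = "mm_ground_truth"
    )
  })
}

#' @export
print.mm_ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground truth: %d cells x %d frames, %d slingshot events\n",
    x$params$n_cells, x$params$n_frames,
    sum(lengths(x$slingshot_frames))
  ))
  invisible(x)
}

#' Write / read ground truth as CSV
#'
#' Columns: `track_id, frame, x_px, y_px, circularity, elongation,
#' is_slingshot`; frames 0-based, x = column, y = row, origin top-left.
#'
#' @param truth An `mm_ground_truth` object (or its `data` tibble).
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  d <- if (inherits(truth, "mm_ground_truth")) truth$data else truth
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  d <- read.csv(path)
  need <- c("track_id", "frame", "x_px", "y_px", "circularity",
            "elongation", "is_slingshot")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("ground-truth CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(d[need])
}

#' Extract per-cell tracks from ground truth
#'
#' @param truth An `mm_ground_truth` object.
#' @return A list of `mm_track` objects (see [as_track()]).
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  d <- truth$data
  lapply(split(d, d$track_id), function(g) {
    as_track(g$frame, g$x_px, g$y_px,
             track_id = g$track_id[1],
             calibration = truth$params$calibration)
  })
}

#' Extract per-cell circularity series from ground truth
#'
#' @param truth An `mm_ground_truth` object.
#' @return A named list of numeric circularity vectors, one per cell, in
#'   frame order.
#' @export
truth_shape_series <- function(truth) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  d <- truth$data
  lapply(split(d, d$track_id), function(g) g$circularity[order(g$frame)])
}
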