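# Rendering of synthetic microscopy data: tracker-dye movies, confocal
# z-stacks, and pre/post-wash adhesion fields.

# Add one elliptical Gaussian spot to a frame, in place on a local window.
# x, y are 0-based pixel-centre coordinates (x = column, y = row).
add_spot <- function(frame, x, y, sigma, elongation, theta, integrated) {
  sx <- sigma * sqrt(elongation)
  sy <- sigma / sqrt(elongation)
  amp <- integrated / (2 * pi * sx * sy)
  r <- ceiling(3 * sx) + 1L
  nr <- nrow(frame); nc <- ncol(frame)
  i0 <- max(1L, floor(y + 1 - r)); i1 <- min(nr, ceiling(y + 1 + r))
  j0 <- max(1L, floor(x + 1 - r)); j1 <- min(nc, ceiling(x + 1 + r))
  if (i0 > i1 || j0 > j1) return(frame)
  ii <- i0:i1; jj <- j0:j1
  dy <- ii - 1 - y
  dx <- jj - 1 - x
  # rotate into the spot frame (major axis along heading theta)
  ct <- cos(theta); st <- sin(theta)
  u <- outer(dy, dx, function(a, b) b * ct + a * st)
  v <- outer(dy, dx, function(a, b) -b * st + a * ct)
  frame[ii, jj] <- frame[ii, jj] + amp * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
  frame
}

#' Render a ground-truth simulation as a fluorescence movie
#'
#' Each visible cell is drawn as an elliptical Gaussian spot of constant
#' integrated intensity whose axis ratio encodes the frame's elongation and
#' whose major axis follows the instantaneous heading. Cells are omitted per
#' frame with probability `detection_dropout_prob`; additive Gaussian
#' background noise is applied. Intensities are on the [0, 1] scale used by
#' 16-bit TIFF export.
#'
#' @param truth An `mm_ground_truth` from [simulate_tracks()].
#' @param params The [sim_params()] used to generate `truth` (defaults to the
#'   ones stored in `truth`).
#' @param spot_sigma Geometric-mean Gaussian sigma of a round spot, pixels.
#' @param spot_intensity Integrated spot intensity (sum over pixels).
#' @param background Constant background level.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @return A numeric array `[rows, cols, frames]` with attributes
#'   `calibration` and `dropped` (logical cells x frames matrix of omitted
#'   detections).
#' @export
render_movie <- function(truth, params = truth$params,
                         spot_sigma = 3, spot_intensity = 25,
                         background = 0.05, noise_sd = 0.01) {
  stopifnot(inherits(truth, "mm_ground_truth"))
  check_scalar(spot_sigma, "spot_sigma", lo = 0.5)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  w <- params$field_size[1]; h <- params$field_size[2]
  if (min(w, h) < 6 * spot_sigma) {
    stop("field too small for the requested spot size", call. = FALSE)
  }
  nf <- params$n_frames
  d <- truth$data
  # heading per (cell, frame): direction of the step leaving the frame
  with_seed(params$seed + 7919L, {
    dropped <- matrix(FALSE, nrow = params$n_cells, ncol = nf)
    if (params$detection_dropout_prob > 0 && params$n_cells > 0) {
      dropped[] <- runif(params$n_cells * nf) < params$detection_dropout_prob
    }
    stack <- array(background, dim = c(h, w, nf))
    if (nrow(d) > 0) {
      split_cells <- split(d, d$track_id)
      for (ci in seq_along(split_cells)) {
        g <- split_cells[[ci]]
        g <- g[order(g$frame), ]
        dx <- diff(g$x_px); dy <- diff(g$y_px)
        theta <- atan2(c(dy, if (length(dy)) dy[length(dy)] else 0),
                       c(dx, if (length(dx)) dx[length(dx)] else 1))
        for (k in seq_len(nrow(g))) {
          f <- g$frame[k] + 1L
          if (dropped[ci, f]) next
          stack[, , f] <- add_spot(
            stack[, , f], g$x_px[k], g$y_px[k],
            sigma = spot_sigma, elongation = g$elongation[k],
            theta = theta[k], integrated = spot_intensity
          )
        }
      }
    }
    if (noise_sd > 0) {
      stack <- stack + array(rnorm(length(stack), 0, noise_sd), dim = dim(stack))
    }
    stack <- pmin(pmax(stack, 0), 1)
    attr(stack, "calibration") <- params$calibration
    attr(stack, "dropped") <- dropped
    stack
  })
}

#' Write / read an image stack as multi-page 16-bit TIFF
#'
#' Page order is time (movies) or z ascending from the ventral slice
#' (stacks). The calibration travels in a YAML sidecar (`<path>.yaml`) so it
#' survives tools that strip TIFF tags.
#'
#' @param stack Numeric array `[rows, cols, pages]`, values in [0, 1].
#' @param path File path.
#' @param calibration Optional [calibration()] recorded in the sidecar.
#' @export
write_stack_tiff <- function(stack, path, calibration = attr(stack, "calibration")) {
  stopifnot(length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!is.null(calibration)) {
    yaml::write_yaml(
      list(microns_per_pixel = calibration$microns_per_pixel,
           minutes_per_frame = calibration$minutes_per_frame),
      paste0(path, ".yaml")
    )
  }
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) stack[, , k] <- pages[[k]]
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    attr(stack, "calibration") <- calibration(
      meta$microns_per_pixel, meta$minutes_per_frame
    )
  }
  stack
}

#' Simulate a confocal z-stack of one stained cell
#'
#' The ventral (z = 0, coverslip-proximal) slice carries
#' `ventral_fraction * total_intensity`; the remainder is split evenly among
#' the other slices. Within each slice the signal is spread over a disk-shaped
#' cell footprint, and i.i.d. Gaussian pixel noise is added.
#'
#' @param n_slices Number of z slices (>= 2).
#' @param ventral_fraction Fraction of total signal in the bottom slice,
#'   in [0, 1].
#' @param total_intensity Total integrated signal over the whole stack
#'   (arbitrary photon-count units). Must be >= 0.
#' @param noise_sd Per-pixel Gaussian noise sd, same units.
#' @param dim_px Slice dimensions `c(rows, cols)`.
#' @param cell_radius_px Radius of the disk footprint.
#' @param seed Integer RNG seed.
#' @return A list with `stack` (array rows x cols x n_slices), `mask` (the
#'   logical footprint used for all slices), and `true_profile` (noise-free
#'   per-slice integrated intensities, ventral first).
#' @export
simulate_zstack <- function(n_slices, ventral_fraction, total_intensity,
                            noise_sd = 0, dim_px = c(64, 64),
                            cell_radius_px = 20, seed = 1L) {
  n_slices <- check_count(n_slices, "n_slices", min = 2L)
  check_scalar(ventral_fraction, "ventral_fraction", lo = 0, hi = 1)
  check_scalar(total_intensity, "total_intensity", lo = 0)
  check_scalar(noise_sd, "noise_sd", lo = 0)
  profile <- rep(total_intensity * (1 - ventral_fraction) / (n_slices - 1), n_slices)
  profile[1] <- total_intensity * ventral_fraction
  cy <- (dim_px[1] - 1) / 2; cx <- (dim_px[2] - 1) / 2
  mask <- outer(seq_len(dim_px[1]) - 1 - cy, seq_len(dim_px[2]) - 1 - cx,
                function(a, b) a^2 + b^2 <= cell_radius_px^2)
  npx <- sum(mask)
  with_seed(seed, {
    stack <- array(0, dim = c(dim_px[1], dim_px[2], n_slices))
    for (z in seq_len(n_slices)) {
      sl <- matrix(0, dim_px[1], dim_px[2])
      sl[mask] <- profile[z] / npx
      if (noise_sd > 0) sl <- sl + matrix(rnorm(length(sl), 0, noise_sd), dim_px[1])
      stack[, , z] <- sl
    }
    list(stack = stack, mask = mask, true_profile = profile)
  })
}

#' Simulate a pre/post-wash adhesion field
#'
#' Cell positions before the wash are uniform in the field; each cell is
#' independently detached (removed from the post-wash field) with probability
#' `detach_prob`.
#'
#' @param n_pre Number of cells before the wash.
#' @param detach_prob Per-cell detachment probability, in [0, 1].
#' @param seed Integer RNG seed.
#' @param field_size Field dimensions `c(width, height)` in pixels.
#' @return A list with `pre` and `post`, each an n x 2 matrix of (x, y)
#'   positions, and `detached`, the logical removal indicator.
#' @export
simulate_adhesion_field <- function(n_pre, detach_prob, seed = 1L,
                                    field_size = c(1024, 1024)) {
  n_pre <- check_count(n_pre, "n_pre", min = 0L)
  check_scalar(detach_prob, "detach_prob", lo = 0, hi = 1)
  with_seed(seed, {
    pre <- cbind(
      x = runif(n_pre, 0, field_size[1] - 1),
      y = runif(n_pre, 0, field_size[2] - 1)
    )
    detached <- runif(n_pre) < detach_prob
    list(pre = pre, post = pre[!detached, , drop = FALSE], detached = detached)
  })
}
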