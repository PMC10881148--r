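# Cell shape: circularity, elongation, frame-to-frame shape change and
# slingshot-event detection.

# Subpixel perimeter of a binary mask: marching squares at the 0.5 iso-level
# of a lightly Gaussian-smoothed copy of the mask. The smoothing turns the
# pixel staircase into an interpolable field whose 0.5 level set tracks the
# true region boundary to well under a pixel for smooth shapes; a naive
# pixel-edge perimeter would bias circularity low by up to 4/pi.
perimeter_subpixel <- function(mask, smooth_sigma = 1.2) {
  m <- matrix(0, nrow(mask) + 8L, ncol(mask) + 8L)
  m[5:(4 + nrow(mask)), 5:(4 + ncol(mask))] <- as.numeric(mask)
  s <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(m, smooth_sigma)) else m
  iso <- 0.5
  nr <- nrow(s); nc <- ncol(s)
  a <- s[-nr, -nc]; b <- s[-nr, -1]; d <- s[-1, -nc]; cc <- s[-1, -1]
  case <- (a > iso) + 2L * (b > iso) + 4L * (cc > iso) + 8L * (d > iso)
  cells <- which(case > 0L & case < 15L, arr.ind = TRUE)
  if (nrow(cells) == 0L) return(0)
  total <- 0
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    va <- s[i, j]; vb <- s[i, j + 1]; vc <- s[i + 1, j + 1]; vd <- s[i + 1, j]
    # edge crossing points in (x, y) local coordinates of the cell;
    # top edge a-b, right b-c, bottom d-c, left a-d
    tx <- function(v1, v2) (iso - v1) / (v2 - v1)
    pts <- list(
      top    = if ((va > iso) != (vb > iso)) c(tx(va, vb), 0) else NULL,
      right  = if ((vb > iso) != (vc > iso)) c(1, tx(vb, vc)) else NULL,
      bottom = if ((vd > iso) != (vc > iso)) c(tx(vd, vc), 1) else NULL,
      left   = if ((va > iso) != (vd > iso)) c(0, tx(va, vd)) else NULL
    )
    pts <- Filter(Negate(is.null), pts)
    if (length(pts) == 2L) {
      total <- total + sqrt(sum((pts[[1]] - pts[[2]])^2))
    } else if (length(pts) == 4L) {
      # saddle: disambiguate by the centre value
      centre_in <- mean(c(va, vb, vc, vd)) > iso
      corner_a_in <- va > iso
      if (centre_in == corner_a_in) {
        total <- total + sqrt(sum((pts$top - pts$right)^2)) +
          sqrt(sum((pts$left - pts$bottom)^2))
      } else {
        total <- total + sqrt(sum((pts$top - pts$left)^2)) +
          sqrt(sum((pts$right - pts$bottom)^2))
      }
    }
  }
  total
}

check_mask <- function(mask, require_connected = TRUE) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- mask > 0
  if (!any(m)) stop("mask is empty", call. = FALSE)
  if (require_connected) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(m * 1)))
    if (max(lab) > 1) stop("mask has multiple connected regions", call. = FALSE)
  }
  m
}

#' Circularity from area and perimeter (closed form)
#'
#' `4 * pi * area / perimeter^2`, clipped to at most 1. Equals 1 for a
#' perfect circle and pi/4 for a square; decreases with elongation or
#' contour roughness.
#'
#' @param area Region area.
#' @param perimeter Region perimeter, same length unit.
#' @return Dimensionless circularity in [0, 1].
#' @examples
#' circ_index(pi * 5^2, 2 * pi * 5) # circle: 1
#' circ_index(4, 8)                 # unit-ish square: pi / 4
#' @export
circ_index <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive", call. = FALSE)
  }
  pmin(4 * pi * area / perimeter^2, 1)
}

#' Circularity of a binary mask
#'
#' Area is the pixel count; the perimeter is measured on a subpixel
#' marching-squares contour of the region (see the package vignette for the
#' estimator). The result is clipped to at most 1.
#'
#' @param mask Logical or 0/1 matrix holding a single connected region.
#' @return Dimensionless circularity in [0, 1].
#' @export
circularity <- function(mask) {
  m <- check_mask(mask)
  circ_index(sum(m), perimeter_subpixel(m))
}

#' Elongation of a binary mask
#'
#' Ratio of the major to the minor axis of the region's second-moment
#' (equivalent) ellipse; always >= 1, with 1 for a disk. Degenerate regions
#' (zero minor axis, e.g. a one-pixel-wide line) give NA.
#'
#' @param mask Logical or 0/1 matrix with positive area.
#' @return Dimensionless axis ratio >= 1, or NA.
#' @export
elongation <- function(mask) {
  m <- check_mask(mask, require_connected = FALSE)
  idx <- which(m, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  mu20 <- mean((x - mean(x))^2)
  mu02 <- mean((y - mean(y))^2)
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  # + 1/12: variance of the unit square pixel footprint, so a single pixel
  # is a square, not a point
  mu20 <- mu20 + 1 / 12
  mu02 <- mu02 + 1 / 12
  tr <- mu20 + mu02
  det_root <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (tr + det_root) / 2
  l2 <- (tr - det_root) / 2
  if (l2 <= 1e-12) return(NA_real_)
  sqrt(l1 / l2)
}

#' Frame-to-frame shape change of a circularity series
#'
#' Computes the absolute circularity differences `s_n = |C_n - C_{n+1}|`
#' over the analysis window and their mean. The default window of 31 frames
#' corresponds to the 5-hour analysis interval at a 10-minute frame spacing;
#' frames outside the window are excluded.
#'
#' @param circ Numeric circularity series (one value per frame, in [0, 1]).
#' @param window_frames Window length in frames (>= 2); `Inf` uses the whole
#'   series.
#' @param offset 0-based index of the first window frame.
#' @param cell_id Identifier carried into the result.
#' @return An object of class `mm_shape_dynamics`: list with `cell_id`,
#'   `deltas`, and `mean_shape_change`.
#' @examples
#' shape_change(c(0.9, 0.45, 0.9), window_frames = 3)$deltas # 0.45 0.45
#' @export
shape_change <- function(circ, window_frames = 31, offset = 0L, cell_id = 1L) {
  stopifnot(is.numeric(circ))
  if (is.finite(window_frames)) {
    window_frames <- check_count(window_frames, "window_frames", min = 2L)
    idx <- seq.int(offset + 1L, min(length(circ), offset + window_frames))
  } else {
    idx <- seq.int(offset + 1L, length(circ))
  }
  if (length(idx) < 2L) {
    stop("circularity series shorter than 2 frames within the window",
         call. = FALSE)
  }
  w <- circ[idx]
  deltas <- abs(diff(w))
  structure(
    list(cell_id = cell_id, deltas = deltas,
         mean_shape_change = mean(deltas)),
    class = "mm_shape_dynamics"
  )
}

#' Count slingshot events in a shape-dynamics series
#'
#' A slingshot event is a frame-to-frame change in circularity of magnitude
#' greater than or equal to `threshold` (default 0.4, the operational
#' definition used for the recoil behaviour on laminin). The comparison is
#' inclusive.
#'
#' @param dynamics An `mm_shape_dynamics` from [shape_change()], or a raw
#'   numeric vector of absolute deltas.
#' @param threshold Event threshold.
#' @return Integer event count.
#' @export
detect_slingshots <- function(dynamics, threshold = 0.4) {
  deltas <- if (inherits(dynamics, "mm_shape_dynamics")) dynamics$deltas else dynamics
  stopifnot(is.numeric(deltas))
  check_scalar(threshold, "threshold", lo = 0)
  sum(deltas >= threshold)
}

#' Slingshot events per cell in a population
#'
#' Total number of events across all cells divided by the number of cells;
#' the single per-population value reported for each experimental run.
#'
#' @param population A list of `mm_shape_dynamics` (or numeric delta
#'   vectors).
#' @param threshold Event threshold passed to [detect_slingshots()].
#' @return Events per cell (dimensionless).
#' @export
events_per_cell <- function(population, threshold = 0.4) {
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  counts <- vapply(population, detect_slingshots, numeric(1), threshold = threshold)
  sum(counts) / length(population)
}

#' Per-frame cell masks by seeded flood fill
#'
#' Semi-automated stand-in for hand-marking each cell: every frame is
#' thresholded and the mask is the flood-fill basin (connected
#' above-threshold component) containing the seed position, typically the
#' tracked centroid. Touching cells that share a basin are a documented
#' limitation.
#'
#' @param stack Numeric array `[rows, cols, frames]` (fluorescent channel,
#'   cells brighter than background).
#' @param seeds Data frame with columns `frame` (0-based), `x`, `y`
#'   (0-based pixel coordinates).
#' @param threshold Intensity threshold separating cells from background.
#' @return A named list (by frame) of logical masks.
#' @export
trace_masks <- function(stack, seeds, threshold) {
  stopifnot(length(dim(stack)) == 3L,
            all(c("frame", "x", "y") %in% names(seeds)))
  check_scalar(threshold, "threshold")
  out <- list()
  for (k in seq_len(nrow(seeds))) {
    f <- seeds$frame[k] + 1L
    img <- stack[, , f]
    bw <- img > threshold
    i <- round(seeds$y[k]) + 1L
    j <- round(seeds$x[k]) + 1L
    if (i < 1L || j < 1L || i > nrow(bw) || j > ncol(bw) || !bw[i, j]) {
      stop(sprintf("seed (%g, %g) in frame %d is not inside an above-threshold region",
                   seeds$x[k], seeds$y[k], seeds$frame[k]), call. = FALSE)
    }
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
    out[[as.character(seeds$frame[k])]] <- lab == lab[i, j]
  }
  out
}
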