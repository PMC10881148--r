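# Shared fixtures and independent oracles used across test files.

# A grid of well-separated start positions for round-trip tracking tests.
grid_starts <- function(nx, ny, spacing, margin = spacing / 2) {
  as.matrix(expand.grid(
    x = margin + spacing * (seq_len(nx) - 1),
    y = margin + spacing * (seq_len(ny) - 1)
  ))
}

# Random synthetic tracks (not from the walker) for filter-oracle tests.
random_tracks <- function(n, seed, cal = calibration()) {
  with_seed <- get("with_seed", asNamespace("macromigr"))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      np <- sample(2:40, 1)
      f0 <- sample(0:10, 1)
      as_track(
        frame = f0 + cumsum(c(0L, sample(1:3, np - 1, replace = TRUE))),
        x = cumsum(runif(np, -6, 6)),
        y = cumsum(runif(np, -6, 6)),
        track_id = i, calibration = cal
      )
    })
  })
}

# Independent brute-force filter: recomputes the three criteria from the raw
# points without using any package metric helpers.
bruteforce_filter_keep <- function(track, min_dur = 20, min_speed = 2, min_disp = 8) {
  mpp <- track$calibration$microns_per_pixel
  f <- track$frame; x <- track$x * mpp; y <- track$y * mpp
  dur <- max(f) - min(f) + 1
  path <- 0
  for (k in 2:length(f)) path <- path + sqrt((x[k] - x[k - 1])^2 + (y[k] - y[k - 1])^2)
  speed <- path / (max(f) - min(f))
  disp <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  dur >= min_dur && speed >= min_speed && disp >= min_disp
}

# Match ground-truth tracks to recovered tracks by mean position agreement.
# Returns per-truth-track maximum position error (px), or Inf if no recovered
# track covers the same frames.
roundtrip_errors <- function(truth, recovered) {
  tt <- truth_tracks(truth)
  vapply(tt, function(g) {
    best <- Inf
    for (r in recovered) {
      common <- intersect(g$frame, r$frame)
      if (length(common) < length(g$frame)) next
      gi <- match(common, g$frame); ri <- match(common, r$frame)
      err <- max(sqrt((g$x[gi] - r$x[ri])^2 + (g$y[gi] - r$y[ri])^2))
      best <- min(best, err)
    }
    best
  }, numeric(1))
}

# Rasterized ellipse mask (axes in pixels, rotation in radians).
ellipse_mask <- function(nr, nc, cy, cx, a, b, theta = 0) {
  outer(seq_len(nr) - cy, seq_len(nc) - cx, function(dy, dx) {
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}
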