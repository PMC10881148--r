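test_that("simulation is bit-identical under the same seed and parameters", {
  p <- sim_params(n_cells = 6, n_frames = 40, mode = lam_mode(), seed = 42)
  expect_identical(simulate_tracks(p), simulate_tracks(p))
  t1 <- simulate_tracks(p)
  expect_identical(render_movie(t1, p), render_movie(t1, p))
  p2 <- sim_params(n_cells = 6, n_frames = 40, mode = lam_mode(), seed = 43)
  expect_false(identical(simulate_tracks(p2)$data, t1$data))
})

test_that("zero-noise walkers move in straight lines at the nominal speed", {
  m <- mode_params(mean_step_speed = 1, angular_sd = 0, circ_baseline = 0.5,
                   circ_noise_sd = 0, slingshot_rate = 0)
  # central starts: a 29-step ballistic path stays far from the boundary
  p <- sim_params(n_cells = 4, n_frames = 30, field_size = c(4000, 4000),
                  mode = m, seed = 9,
                  start_positions = cbind(rep(2000, 4), rep(2000, 4)))
  tracks <- truth_tracks(simulate_tracks(p))
  for (t in tracks) {
    expect_equal(track_persistence(t), 1, tolerance = 1e-12)
    expect_equal(track_speed(t), 1, tolerance = 1e-9)
  }
})

test_that("mean per-step displacement matches the generator speed (Monte Carlo)", {
  # 1 um/min at 10 min/frame => 10 um steps; >= 10,000 steps, huge field so
  # reflections are impossible
  m <- mode_params(mean_step_speed = 1, angular_sd = 1.2, circ_baseline = 0.6)
  p <- sim_params(n_cells = 110, n_frames = 97, field_size = c(50000, 50000),
                  mode = m, seed = 123)
  d <- simulate_tracks(p)$data
  steps <- do.call(c, lapply(split(d, d$track_id), function(g) {
    sqrt(diff(g$x_px)^2 + diff(g$y_px)^2)
  }))
  expect_gte(length(steps), 10000)
  expect_lt(abs(mean(steps) - 10) / 10, 0.01)
})

test_that("mean circularity and slingshot rate converge to generator values", {
  m <- mode_params(mean_step_speed = 0.5, angular_sd = 1, circ_baseline = 0.7,
                   circ_noise_sd = 0.02, slingshot_rate = 0.5,
                   slingshot_step = 15, slingshot_delta_c = 0.5)
  p <- sim_params(n_cells = 150, n_frames = 97, field_size = c(20000, 20000),
                  mode = m, seed = 77)
  truth <- simulate_tracks(p)
  # circularity: baseline recovered away from event frames and their
  # 4-frame recovery ramps
  d <- truth$data
  quiet <- unlist(lapply(seq_len(p$n_cells), function(i) {
    g <- d[d$track_id == i, ]
    excl <- unique(unlist(lapply(truth$slingshot_frames[[i]],
                                 function(f) f + 0:4)))
    g$circularity[!(g$frame %in% excl)]
  }))
  expect_lt(abs(mean(quiet) - 0.7), 3 * 0.02 / sqrt(length(quiet)) + 0.002)
  # events: Bernoulli draws are suppressed during the 4-frame recovery ramp,
  # so the realised rate is p_eff = p / (1 + p * recovery); 3 sigma band
  n_events <- sum(lengths(truth$slingshot_frames))
  p_frame <- 0.5 * 10 / 60
  n_trials <- 150 * 96
  p_eff <- p_frame / (1 + p_frame * m$recovery_frames)
  expect_lt(abs(n_events - n_trials * p_eff),
            3 * sqrt(n_trials * p_eff * (1 - p_eff)))
})

test_that("injected slingshot frames always carry a true delta >= delta_c", {
  m <- mode_params(mean_step_speed = 1, angular_sd = 1.4, circ_baseline = 0.8,
                   circ_noise_sd = 0.03, slingshot_rate = 2,
                   slingshot_step = 20, slingshot_delta_c = 0.55)
  p <- sim_params(n_cells = 40, n_frames = 60, field_size = c(5000, 5000),
                  mode = m, seed = 5)
  truth <- simulate_tracks(p)
  d <- truth$data
  for (i in seq_len(p$n_cells)) {
    g <- d[d$track_id == i, ]
    for (f in truth$slingshot_frames[[i]]) {
      expect_gte(abs(g$circularity[f + 1] - g$circularity[f]), 0.55 - 1e-12)
    }
  }
  expect_gt(sum(lengths(truth$slingshot_frames)), 0)
})

test_that("invalid generator parameters are rejected", {
  expect_error(mode_params(-1, 0.5, 0.5), "mean_step_speed")
  expect_error(mode_params(1, 0.5, 0), "circ_baseline")
  expect_error(mode_params(1, 0.5, 1.5), "circ_baseline")
  expect_error(mode_params(1, 0.5, 0.3, slingshot_rate = 1,
                           slingshot_delta_c = 0.5), "slingshot_delta_c")
  expect_error(sim_params(n_cells = 5, n_frames = 1), "n_frames")
  expect_error(sim_params(n_cells = 5, detection_dropout_prob = 1),
               "detection_dropout_prob")
  expect_error(calibration(0, 10), "microns_per_pixel")
})

test_that("rendered movies contain the expected spots", {
  starts <- grid_starts(3, 3, 60)
  p <- sim_params(n_cells = 9, n_frames = 3, field_size = c(240, 240),
                  mode = mode_params(0.3, 1, 0.6), seed = 21,
                  start_positions = starts)
  truth <- simulate_tracks(p)
  mv <- render_movie(truth, p, noise_sd = 0.005)
  cfg <- tracking_config(spot_diameter = 8, quality_threshold = 0.2)
  for (f in 1:3) {
    expect_equal(nrow(detect_cells(mv[, , f], cfg)), 9)
  }
  # field too small for the spot
  tiny <- sim_params(n_cells = 1, n_frames = 2, field_size = c(12, 12),
                     seed = 1, boundary_pad_px = 2)
  expect_error(render_movie(simulate_tracks(tiny), tiny, spot_sigma = 4),
               "too small")
})

test_that("dropout removes the binomially expected number of spots", {
  starts <- grid_starts(10, 10, 40)
  p <- sim_params(n_cells = 100, n_frames = 2, field_size = c(440, 440),
                  mode = mode_params(0.1, 1, 0.6), seed = 31,
                  detection_dropout_prob = 0.5, start_positions = starts)
  truth <- simulate_tracks(p)
  mv <- render_movie(truth, p, noise_sd = 0.005)
  visible <- nrow(detect_cells(mv[, , 1], tracking_config(quality_threshold = 0.2)))
  ci <- qbinom(c(0.005, 0.995), 100, 0.5)
  expect_gte(visible, ci[1])
  expect_lte(visible, ci[2])
})

test_that("an empty simulation renders pure background noise", {
  p <- sim_params(n_cells = 0, n_frames = 2, field_size = c(64, 64), seed = 3)
  mv <- render_movie(simulate_tracks(p), p, background = 0.05, noise_sd = 0.01)
  expect_equal(mean(mv), 0.05, tolerance = 0.005)
  expect_equal(sd(as.vector(mv)), 0.01, tolerance = 0.002)
  expect_equal(nrow(detect_cells(mv[, , 1], tracking_config(quality_threshold = 0.2))), 0)
})

test_that("z-stack generator hits its trivial and noisy contracts", {
  # uniform profile when ventral fraction = 1/n
  st <- simulate_zstack(5, 0.2, 1e5, noise_sd = 0, seed = 1)
  expect_equal(st$true_profile, rep(2e4, 5))
  expect_equal(max(abs(apply(st$stack, 3, sum) - 2e4)), 0, tolerance = 1e-6)
  # everything in the ventral slice
  st1 <- simulate_zstack(4, 1, 1e5, noise_sd = 0, seed = 1)
  expect_equal(st1$true_profile, c(1e5, 0, 0, 0))
  expect_error(simulate_zstack(1, 0.5, 1e5), "n_slices")
  expect_error(simulate_zstack(4, 0.5, -1), "total_intensity")
})

test_that("adhesion field detachment follows its Bernoulli model", {
  f0 <- simulate_adhesion_field(200, 0, seed = 2)
  expect_identical(f0$post, f0$pre)
  expect_equal(adhesion_ratio(f0$pre, f0$post)$ratio, 1)
  f1 <- simulate_adhesion_field(200, 1, seed = 2)
  expect_equal(nrow(f1$post), 0)
  f <- simulate_adhesion_field(1000, 0.3, seed = 7)
  ratio <- adhesion_ratio(f$pre, f$post)$ratio
  ci <- qbinom(c(0.005, 0.995), 1000, 0.7) / 1000
  expect_gte(ratio, ci[1])
  expect_lte(ratio, ci[2])
})

test_that("ground truth survives a CSV round trip", {
  p <- sim_params(n_cells = 4, n_frames = 15, mode = lam_mode(), seed = 12)
  truth <- simulate_tracks(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(as.data.frame(back), as.data.frame(truth$data), tolerance = 1e-12)
})

test_that("TIFF stack round trip preserves pixels to 16-bit depth and metadata", {
  p <- sim_params(n_cells = 3, n_frames = 4, field_size = c(64, 64),
                  calibration = calibration(0.65, 10), seed = 8)
  mv <- render_movie(simulate_tracks(p), p)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(mv, path)
  back <- read_stack_tiff(path)
  expect_equal(dim(back), dim(mv))
  expect_lt(max(abs(back - mv)), 1 / 65535)
  expect_equal(attr(back, "calibration")$microns_per_pixel, 0.65)
})
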