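test_that("LoG detection finds a rendered spot with subpixel accuracy", {
  p <- sim_params(n_cells = 1, n_frames = 2, field_size = c(120, 100),
                  seed = 3, start_positions = matrix(c(40, 60), 1))
  truth <- simulate_tracks(p)
  mv <- render_movie(truth, p, noise_sd = 0.005)
  det <- detect_cells(mv[, , 1], tracking_config(quality_threshold = 0.2))
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x - 40), 1)
  expect_lt(abs(det$y - 60), 1)
})

test_that("detection rejects blank and malformed input", {
  expect_equal(nrow(detect_cells(matrix(0, 40, 40),
                                 tracking_config(quality_threshold = 0.01))), 0)
  expect_error(detect_cells(matrix(NA_real_, 10, 10)), "non-finite")
  expect_error(detect_cells(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("25 well-separated spots are each recovered within 1 px", {
  starts <- grid_starts(5, 5, 50)
  p <- sim_params(n_cells = 25, n_frames = 2, field_size = c(300, 300),
                  mode = mode_params(0.2, 1, 0.6), seed = 17,
                  start_positions = starts)
  truth <- simulate_tracks(p)
  mv <- render_movie(truth, p, noise_sd = 0.005)
  det <- detect_cells(mv[, , 1], tracking_config(quality_threshold = 0.2))
  expect_equal(nrow(det), 25)
  g <- truth$data[truth$data$frame == 0, ]
  for (k in seq_len(25)) {
    err <- min(sqrt((det$x - g$x_px[k])^2 + (det$y - g$y_px[k])^2))
    expect_lt(err, 1)
  }
})

test_that("linking honours the maximum link distance inclusively", {
  over <- data.frame(frame = c(0L, 1L), x = c(0, 70.1), y = c(0, 0))
  stubs <- link_tracks(over, keep_singletons = TRUE)
  expect_equal(length(stubs), 2)           # split: two one-point stubs
  expect_equal(length(link_tracks(over)), 0)
  at <- data.frame(frame = c(0L, 1L), x = c(0, 70), y = c(0, 0))
  linked <- link_tracks(at)
  expect_equal(length(linked), 1)
  expect_equal(length(linked[[1]]$frame), 2)
})

test_that("gap closing bridges up to, and not beyond, the maximum frame gap", {
  mkgap <- function(gap) {
    data.frame(frame = c(0L, 1L, 2L + gap, 3L + gap),
               x = c(0, 1, 2 + gap, 3 + gap), y = 0)
  }
  t10 <- link_tracks(mkgap(10L))
  expect_equal(length(t10), 1)
  expect_equal(t10[[1]]$frame, c(0L, 1L, 12L, 13L))
  expect_equal(length(link_tracks(mkgap(11L))), 2)
})

test_that("frame-to-frame assignment matches brute-force enumeration", {
  bf <- get("lap_match_bruteforce", asNamespace("macromigr"))
  lap <- get("lap_match", asNamespace("macromigr"))
  ws <- get("with_seed", asNamespace("macromigr"))
  ws(99, {
    for (rep in 1:40) {
      nr <- sample(1:4, 1); nc <- sample(1:4, 1)
      cost <- matrix(runif(nr * nc, 0, 100), nr, nc)
      cost[runif(nr * nc) < 0.3] <- Inf
      b <- 49
      a1 <- lap(cost, b)
      a2 <- bf(cost, b)
      tot <- function(m) {
        sum(ifelse(is.na(m), b, cost[cbind(seq_along(m), ifelse(is.na(m), 1, m))])) +
          b * (nc - sum(!is.na(m)))
      }
      expect_equal(tot(a1), tot(a2), tolerance = 1e-9)
    }
  })
})

test_that("two crossing cells are linked as the optimal assignment", {
  # cells approach and pass; small steps keep the optimal matching unambiguous
  f <- 0:9
  det <- rbind(
    data.frame(frame = f, x = 10 + 3 * f, y = 20, cell = 1),
    data.frame(frame = f, x = 40 - 3 * f, y = 21, cell = 2)
  )
  tracks <- link_tracks(det[c("frame", "x", "y")])
  expect_equal(length(tracks), 2)
  for (t in tracks) {
    expect_equal(length(t$frame), 10)
    expect_true(all(abs(diff(t$y)) < 0.5)) # never jumps between the two lanes
  }
})

test_that("no link exceeds the distance bound and detections are partitioned", {
  ws <- get("with_seed", asNamespace("macromigr"))
  cfg <- tracking_config(max_link_distance = 25, max_gap_frames = 3)
  ws(7, {
    det <- do.call(rbind, lapply(0:14, function(f) {
      n <- sample(3:8, 1)
      data.frame(frame = f, x = runif(n, 0, 120), y = runif(n, 0, 120))
    }))
  })
  tracks <- link_tracks(det, cfg, keep_singletons = TRUE)
  used <- 0L
  for (t in tracks) {
    used <- used + length(t$frame)
    if (length(t$frame) < 2) next
    steps <- sqrt(diff(t$x)^2 + diff(t$y)^2)
    gaps <- diff(t$frame) - 1L
    expect_true(all(steps <= 25 + 1e-9))
    expect_true(all(gaps <= 3))
  }
  expect_equal(used, nrow(det)) # every detection in exactly one track
})

test_that("track filter equals an independent brute-force filter on 1,000 tracks", {
  tracks <- random_tracks(1000, seed = 2024)
  kept <- filter_tracks(tracks, tracking_config())
  oracle <- Filter(bruteforce_filter_keep, tracks)
  expect_equal(vapply(kept, `[[`, 0L, "track_id"),
               vapply(oracle, `[[`, 0L, "track_id"))
  # idempotent and equal to the conjunction of single-criterion filters
  expect_identical(filter_tracks(kept, tracking_config()), kept)
  only <- function(...) filter_tracks(tracks, tracking_config(...))
  conj <- intersect(
    intersect(
      vapply(only(min_mean_speed = 0, min_displacement = 0), `[[`, 0L, "track_id"),
      vapply(only(min_duration_frames = 0, min_displacement = 0), `[[`, 0L, "track_id")
    ),
    vapply(only(min_duration_frames = 0, min_mean_speed = 0), `[[`, 0L, "track_id")
  )
  expect_equal(vapply(kept, `[[`, 0L, "track_id"), conj)
})

test_that("filter thresholds are inclusive at the documented boundaries", {
  cal <- calibration(1, 10)
  # 20 frames spanned, speed exactly 2.00 units/frame, displacement 38 >= 8
  exact <- as_track(0:19, seq(0, 38, by = 2), rep(0, 20), calibration = cal)
  expect_equal(length(filter_tracks(list(exact), tracking_config())), 1)
  # 19 frames spanned, otherwise passing
  short <- as_track(0:18, seq(0, 36, by = 2), rep(0, 19), calibration = cal)
  expect_equal(length(filter_tracks(list(short), tracking_config())), 0)
  # displacement boundary, isolated with the speed criterion disabled
  disp_of <- function(d) as_track(0:19, seq(0, d, length.out = 20), rep(0, 20),
                                  calibration = cal)
  cfg_disp <- tracking_config(min_mean_speed = 0)
  expect_equal(length(filter_tracks(list(disp_of(8.00)), cfg_disp)), 1)
  expect_equal(length(filter_tracks(list(disp_of(7.99)), cfg_disp)), 0)
  # speed below 2.00 rejected
  slow <- as_track(0:19, seq(0, 19, by = 1), rep(0, 20), calibration = cal)
  expect_equal(length(filter_tracks(list(slow), tracking_config())), 0)
})

test_that("track CSV round trip is lossless and tolerant of extra columns", {
  tracks <- random_tracks(5, seed = 55)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tracks, path)
  back <- read_tracks(path)
  expect_equal(length(back), 5)
  for (k in 1:5) {
    expect_equal(back[[k]]$frame, tracks[[k]]$frame)
    expect_equal(back[[k]]$x, tracks[[k]]$x, tolerance = 1e-6)
    expect_equal(back[[k]]$y, tracks[[k]]$y, tolerance = 1e-6)
  }
  # TrackMate-dialect export: extra columns are ignored
  dialect <- withr::local_tempfile(fileext = ".csv")
  tab <- utils::read.csv(path)
  tab$TRACK_INDEX <- seq_len(nrow(tab))
  tab$QUALITY <- 1.0
  tab$POSITION_T <- tab$frame * 600
  utils::write.csv(tab, dialect, row.names = FALSE)
  back2 <- read_tracks(dialect)
  expect_equal(tracks_to_table(back2), tracks_to_table(back))
  # missing column is a schema error naming the column
  broken <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab[setdiff(names(tab), "y")], broken, row.names = FALSE)
  expect_error(read_tracks(broken), "y")
  # non-monotone frames rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(track_id = 1, frame = c(0, 2, 1), x = 1:3, y = 1:3),
                   bad, row.names = FALSE)
  expect_error(read_tracks(bad), "non-monotone")
})
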