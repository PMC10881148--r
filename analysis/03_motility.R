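#!/usr/bin/env Rscript
# Velocity and persistence (d/T) per cell for each condition and run,
# summarized superplot-style (per-run means +/- SEM, per-condition grand
# means) and compared with the Mann-Whitney test.

suppressPackageStartupMessages(library(macromigr))

files <- list.files("results/data", pattern = "^truth_(FN|LAM)_run\\d\\.csv$",
                    full.names = TRUE)
metrics <- NULL
for (f in files) {
  cname <- sub("^truth_([A-Z]+)_run(\\d)\\.csv$", "\\1", basename(f))
  run <- sub("^truth_([A-Z]+)_run(\\d)\\.csv$", "run\\2", basename(f))
  truth <- read_ground_truth(f)
  tracks <- table_to_tracks(
    data.frame(track_id = truth$track_id, frame = truth$frame,
               x = truth$x_px, y = truth$y_px)
  )
  tm <- track_metrics(tracks)
  tm$condition <- cname
  tm$run <- run
  metrics <- rbind(metrics, tm)
}
write.csv(metrics, "results/metrics.csv", row.names = FALSE)

for (metric in c("mean_speed_um_min", "persistence")) {
  gm <- grouped_measurements(metrics[[metric]], metrics$condition,
                             metrics$run, metrics$track_id, metric)
  s <- summarize_superplot(gm)
  write.csv(s$runs, sprintf("results/superplot_%s.csv", metric), row.names = FALSE)
  cmp <- compare_groups(gm, "mann_whitney")
  message(sprintf("%s: FN grand mean %.3f, LAM grand mean %.3f, Mann-Whitney p = %.3g",
                  metric,
                  s$conditions$grand_mean[s$conditions$condition == "FN"],
                  s$conditions$grand_mean[s$conditions$condition == "LAM"],
                  cmp$p_value))
}
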