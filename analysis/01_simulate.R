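#!/usr/bin/env Rscript
# Generate the synthetic study data: three experimental runs per substrate
# condition (fibronectin-like: slow/persistent; laminin-like: fast/meandering
# with slingshot recoils), each an overnight movie's worth of ground-truth
# tracks and shape series, plus one small rendered demo movie for the
# detection/linking demonstration in 02_track.R.

suppressPackageStartupMessages(library(macromigr))

seed <- 20260922L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

conditions <- list(FN = fn_mode(), LAM = lam_mode())
for (cname in names(conditions)) {
  for (run in 1:3) {
    p <- sim_params(
      n_cells = 50, n_frames = 97, field_size = c(12000, 12000),
      mode = conditions[[cname]], seed = seed + 100L * match(cname, names(conditions)) + run
    )
    truth <- simulate_tracks(p)
    write_ground_truth(truth, file.path(out, sprintf("truth_%s_run%d.csv", cname, run)))
    message(sprintf("%s run %d: %d cells, %d slingshot events",
                    cname, run, p$n_cells, sum(lengths(truth$slingshot_frames))))
  }
}

# small rendered movie (grid starts keep cells separated for the round trip)
starts <- as.matrix(expand.grid(x = 85 + 170 * 0:4, y = 85 + 170 * 0:2))
pd <- sim_params(
  n_cells = 15, n_frames = 97, field_size = c(850, 510),
  mode = mode_params(0.3, 1.8, 0.6), seed = seed, start_positions = starts
)
truth_demo <- simulate_tracks(pd)
write_ground_truth(truth_demo, file.path(out, "truth_demo_movie.csv"))
write_stack_tiff(render_movie(truth_demo, pd, noise_sd = 0.005),
                 file.path(out, "demo_movie.tif"))
message("wrote demo movie: 15 cells x 97 frames, ", file.path(out, "demo_movie.tif"))
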