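# Superplot summaries, group comparisons, and pipeline orchestration.

#' Tag per-cell measurements with condition, run and metric
#'
#' @param value Numeric measurement per cell/track.
#' @param condition Condition label (e.g. substrate).
#' @param run Experimental run / replicate identifier.
#' @param id Cell or track identifier.
#' @param metric Metric name.
#' @return A tibble of class `mm_grouped` with one record per measurement.
#' @export
grouped_measurements <- function(value, condition, run, id, metric = "value") {
  stopifnot(is.numeric(value))
  n <- length(value)
  d <- tibble::tibble(
    value = value,
    condition = rep_len(as.character(condition), n),
    run = rep_len(as.character(run), n),
    id = rep_len(as.character(id), n),
    metric = rep_len(as.character(metric), n)
  )
  if (anyNA(d$condition) || anyNA(d$run)) {
    stop("every record needs condition and run tags", call. = FALSE)
  }
  class(d) <- c("mm_grouped", class(d))
  d
}

#' Superplot summary: per-run means with SEM, per-condition grand means
#'
#' For each (condition, run) cell the mean, standard error of the mean
#' (sd / sqrt(n), NA when a run has fewer than 2 cells) and n; for each
#' condition the grand mean of the run means (not the pooled per-cell mean).
#'
#' @param data An `mm_grouped` tibble (or any data frame with `value`,
#'   `condition`, `run` columns).
#' @return A list with tibbles `runs` (condition, run, mean, sem, n) and
#'   `conditions` (condition, grand_mean, n_runs, n_cells).
#' @examples
#' d <- grouped_measurements(c(1, 2, 3), "FN", "run1", 1:3)
#' summarize_superplot(d)$runs
#' @export
summarize_superplot <- function(data) {
  stopifnot(all(c("value", "condition", "run") %in% names(data)))
  if (nrow(data) == 0L) stop("no measurements", call. = FALSE)
  key <- interaction(data$condition, data$run, drop = TRUE, sep = "\r")
  runs <- do.call(rbind, lapply(split(data, key), function(g) {
    tibble::tibble(
      condition = g$condition[1], run = g$run[1],
      mean = mean(g$value),
      sem = if (nrow(g) >= 2L) sd(g$value) / sqrt(nrow(g)) else NA_real_,
      n = nrow(g)
    )
  }))
  rownames(runs) <- NULL
  conditions <- do.call(rbind, lapply(split(runs, runs$condition), function(g) {
    tibble::tibble(
      condition = g$condition[1],
      grand_mean = mean(g$mean),
      n_runs = nrow(g),
      n_cells = sum(g$n)
    )
  }))
  rownames(conditions) <- NULL
  list(runs = runs, conditions = conditions)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z-tests on mean ranks with the standard tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N (N + 1) / 12 - T) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t) / (12 (N - 1))` over tie groups. Two-sided
#' p-values are adjusted across the pairwise family.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"holm"`).
#' @return A list: `z`, `p`, `p_adjusted` (symmetric matrices), `n`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  base_var <- N * (N + 1) / 12 - tie_term
  lv <- levels(groups)
  z <- p <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  pairs <- utils::combn(k, 2)
  zvec <- pvec <- numeric(ncol(pairs))
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    se <- sqrt(base_var * (1 / n[i] + 1 / n[j]))
    zij <- (rbar[i] - rbar[j]) / se
    zvec[c0] <- zij
    pvec[c0] <- 2 * pnorm(-abs(zij))
  }
  padj <- p.adjust(pvec, method = p_adjust)
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    z[i, j] <- z[j, i] <- zvec[c0]
    p[i, j] <- p[j, i] <- pvec[c0]
  }
  padj_m <- p
  for (c0 in seq_len(ncol(pairs))) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    padj_m[i, j] <- padj_m[j, i] <- padj[c0]
  }
  list(z = z, p = p, p_adjusted = padj_m, n = as.integer(n))
}

#' Compare measurement groups with the study's statistical toolkit
#'
#' Dispatches to the named test: `kruskal_dunn` (Kruskal-Wallis omnibus with
#' Dunn's pairwise post-hoc), `mann_whitney` (two-sample Wilcoxon rank-sum),
#' `welch_t` (unpaired t with Welch correction), or `anova` (one-way).
#' Which test fits which design (non-normal multi-group, non-normal
#' two-group, normal two-group, normal multi-group) is the caller's explicit
#' choice; no automatic normality-based selection is performed.
#'
#' @param data An `mm_grouped` tibble, or a data frame with `value` and
#'   `condition` columns.
#' @param design One of `"kruskal_dunn"`, `"mann_whitney"`, `"welch_t"`,
#'   `"anova"`.
#' @param p_adjust Adjustment for Dunn pairwise p-values (default Holm).
#' @return A list of class `mm_comparison`: `test`, `statistic`, `p_value`,
#'   `pairwise` (adjusted p matrix, kruskal_dunn only), `group_ns`.
#' @examples
#' d <- grouped_measurements(c(rnorm(20), rnorm(20, 2)),
#'                           rep(c("FN", "LAM"), each = 20), "run1", 1:40)
#' compare_groups(d, "mann_whitney")$p_value
#' @export
compare_groups <- function(data,
                           design = c("kruskal_dunn", "mann_whitney",
                                      "welch_t", "anova"),
                           p_adjust = "holm") {
  design <- match.arg(design)
  stopifnot(all(c("value", "condition") %in% names(data)))
  g <- factor(data$condition)
  v <- data$value
  ns <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs at least 2 values", call. = FALSE)
  if (design %in% c("mann_whitney", "welch_t") && nlevels(g) != 2L) {
    stop(design, " requires exactly 2 groups", call. = FALSE)
  }
  out <- switch(design,
    kruskal_dunn = {
      kw <- kruskal.test(v, g)
      dn <- dunn_test(v, g, p_adjust = p_adjust)
      list(test = "Kruskal-Wallis + Dunn", statistic = unname(kw$statistic),
           p_value = kw$p.value, pairwise = dn$p_adjusted)
    },
    mann_whitney = {
      w <- wilcox.test(v ~ g, exact = FALSE, correct = TRUE)
      list(test = "Mann-Whitney", statistic = unname(w$statistic),
           p_value = w$p.value, pairwise = NULL)
    },
    welch_t = {
      tt <- t.test(v ~ g, var.equal = FALSE)
      list(test = "Welch t", statistic = unname(tt$statistic),
           p_value = tt$p.value, pairwise = NULL)
    },
    anova = {
      a <- summary(aov(v ~ g))[[1]]
      list(test = "one-way ANOVA", statistic = a$`F value`[1],
           p_value = a$`Pr(>F)`[1], pairwise = NULL)
    }
  )
  out$group_ns <- as.integer(ns)
  names(out$group_ns) <- levels(g)
  class(out) <- "mm_comparison"
  out
}

#' @export
print.mm_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_ns, collapse = "/")))
  invisible(x)
}

#' Run the full simulate-track-measure-compare pipeline
#'
#' Executes detect -> link -> filter -> motility metrics -> shape dynamics ->
#' statistics for each configured condition and writes tidy CSV outputs plus
#' a JSON manifest. Deterministic given the seed.
#'
#' The configuration (YAML file or list) has keys: `seed`; `calibration`
#' (`microns_per_pixel`, `minutes_per_frame`); `conditions`, a named list
#' where each entry has `preset` (`"fn"` or `"lam"`) or explicit mode
#' parameters, plus `n_cells`, `n_frames`, `n_runs`; `tracking` (overrides
#' for [tracking_config()] fields); `shape` (`window_frames`, `threshold`);
#' `from_movies` (logical: render movies and recover tracks by
#' detection/linking rather than using generator tracks directly);
#' `comparisons`, a list of `(metric, test)` pairs; `output_dir`.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @return Invisibly, a list with `metrics`, `dynamics`, `summary`, `stats`,
#'   and `manifest`; CSV/JSON files are written when `output_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$conditions) || length(config$conditions) < 1L) {
    stop("config error: no `conditions`", call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else check_count(config$seed, "seed")
  cal <- if (is.null(config$calibration)) calibration() else
    calibration(config$calibration$microns_per_pixel %||% 1,
                config$calibration$minutes_per_frame %||% 10)
  tcfg_args <- config$tracking %||% list()
  tcfg <- do.call(tracking_config, tcfg_args)
  window_frames <- config$shape$window_frames %||% 31
  sl_threshold <- config$shape$threshold %||% 0.4
  from_movies <- isTRUE(config$from_movies)

  metrics <- dynamics <- NULL
  counts <- list()
  cond_names <- names(config$conditions)
  if (is.null(cond_names)) stop("config error: conditions must be named", call. = FALSE)
  for (ci in seq_along(config$conditions)) {
    cname <- cond_names[ci]
    cc <- config$conditions[[ci]]
    mode <- if (!is.null(cc$preset)) {
      switch(tolower(cc$preset), fn = fn_mode(), lam = lam_mode(),
             stop("config error: unknown preset ", cc$preset, call. = FALSE))
    } else {
      do.call(mode_params, cc$mode)
    }
    n_runs <- cc$n_runs %||% 1L
    for (run in seq_len(n_runs)) {
      run_seed <- seed + 1000L * ci + run
      sp <- sim_params(
        n_cells = cc$n_cells %||% 50L, n_frames = cc$n_frames %||% 97L,
        field_size = unlist(cc$field_size %||% c(800, 800)),
        calibration = cal, mode = mode, seed = run_seed
      )
      truth <- simulate_tracks(sp)
      tracks <- if (from_movies) {
        stack <- render_movie(truth, sp)
        filter_tracks(link_tracks(detect_movie(stack, tcfg), tcfg, cal), tcfg)
      } else {
        filter_tracks(truth_tracks(truth), tcfg)
      }
      counts[[paste(cname, run, sep = "/")]] <- list(
        cells_simulated = sp$n_cells, tracks_filtered = length(tracks)
      )
      tm <- track_metrics(tracks)
      if (nrow(tm)) {
        tm$condition <- cname
        tm$run <- paste0("run", run)
        metrics <- rbind(metrics, tm)
      }
      dyns <- lapply(truth_shape_series(truth), shape_change,
                     window_frames = window_frames)
      dy <- tibble::tibble(
        cell_id = seq_along(dyns),
        mean_shape_change = vapply(dyns, `[[`, 0, "mean_shape_change"),
        slingshot_count = vapply(dyns, detect_slingshots, 0,
                                 threshold = sl_threshold),
        condition = cname, run = paste0("run", run)
      )
      dynamics <- rbind(dynamics, dy)
    }
  }

  gm <- grouped_measurements(metrics$mean_speed_um_min, metrics$condition,
                             metrics$run, metrics$track_id, "mean_speed")
  summary_tab <- summarize_superplot(gm)

  stats <- list()
  for (cmp in (config$comparisons %||% list())) {
    metric <- cmp$metric
    vals <- switch(metric,
      mean_speed = metrics$mean_speed_um_min,
      persistence = metrics$persistence,
      mean_shape_change = dynamics$mean_shape_change,
      slingshot_count = dynamics$slingshot_count,
      stop("config error: unknown comparison metric ", metric, call. = FALSE)
    )
    conds <- if (metric %in% c("mean_shape_change", "slingshot_count")) {
      dynamics$condition
    } else {
      metrics$condition
    }
    res <- compare_groups(data.frame(value = vals, condition = conds),
                          design = cmp$test %||% "mann_whitney")
    stats[[paste(metric, res$test, sep = ": ")]] <- list(
      metric = metric, test = res$test, statistic = res$statistic,
      p_value = res$p_value, group_ns = as.list(res$group_ns)
    )
  }

  manifest <- list(
    package = "macromigr",
    version = as.character(utils::packageVersion("macromigr")),
    seed = seed,
    calibration = list(microns_per_pixel = cal$microns_per_pixel,
                       minutes_per_frame = cal$minutes_per_frame),
    tracking = unclass(tcfg),
    shape = list(window_frames = window_frames, threshold = sl_threshold),
    from_movies = from_movies,
    stage_counts = counts
  )

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(config$output_dir, f)
    write.csv(metrics, fp("metrics.csv"), row.names = FALSE)
    write.csv(dynamics, fp("dynamics.csv"), row.names = FALSE)
    write.csv(summary_tab$runs, fp("summary.csv"), row.names = FALSE)
    jsonlite::write_json(stats, fp("stats.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(metrics = metrics, dynamics = dynamics,
                 summary = summary_tab, stats = stats, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
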