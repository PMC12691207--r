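# End-to-end orchestration: simulate -> features -> zones -> statistics ->
# report, plus deterministic fixture generation for tests and examples.

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a cohort, extracts per-run and frame-pooled feature tables,
#' builds the Block-2 vs Block-3 proportion-of-density curves, detects the
#' decision zone and the region of behavioral uncertainty, and runs the
#' inference layer: discriminant analysis on the test-run features,
#' per-fish second-level Wilcoxon tests, the longest-trajectory
#' rank-sum comparison, the activity variance (Levene) test, Cohen's d and
#' ROC AUC. Deterministic given the seed.
#'
#' @param config An [experiment_config()].
#' @param seed Master integer seed.
#' @param n_fish Cohort size.
#' @param sampler A [policy_sampler()] (or fixed `fish_policy`).
#' @param out_dir Optional directory; when given, feature tables (CSV),
#'   curves (CSV) and the report (JSON) are written there.
#' @return A list of class `run_report` with elements `seed`, `n_fish`,
#'   `test_runs`, `features` (per-run), `frame_features`, `curves`
#'   (block-2/3 proportion curves), `zone`, `uncertainty`, `stats` and
#'   `warnings`, plus `paths` when `out_dir` is given.
#' @export
run_full <- function(config = experiment_config(), seed = 1L, n_fish = 21L,
                     sampler = policy_sampler(), out_dir = NULL) {
  warnings <- character(0)
  sessions <- simulate_cohort(n_fish, config, sampler, seed = seed)
  n_runs <- config$n_blocks * config$runs_per_block
  test_runs <- (n_runs - config$runs_per_block + 1L):n_runs

  features <- extract_features_cohort(sessions, config)
  frame_features <- extract_features_cohort(sessions, config,
                                            pooling = "frame",
                                            runs = test_runs)

  # positional density during the gap, block 2 vs block 3
  curves <- lapply(c(2L, 3L), function(b) {
    ff <- do.call(rbind, lapply(sessions, function(s) {
      fr <- s$frames
      if (!"speed" %in% names(fr)) fr <- compute_series(fr, config$fps)
      fr[fr$epoch_kind == "gap" & !is.na(fr$block_id) & fr$block_id == b, ,
         drop = FALSE]
    }))
    ff <- filter_edges(ff, config$backend_margin, config$screen_margin,
                       config$tank)
    dc <- location_density(ff$distance, ff$cue,
                           range = c(config$screen_margin,
                                     config$tank$length - config$backend_margin))
    proportion_curve(dc)
  })
  names(curves) <- c("block2", "block3")
  block3_has_both <- length(unique(
    features$cue[features$run_index %in% test_runs])) == 2L
  zone <- if (block3_has_both)
    tryCatch(detect_decision_zone(curves$block3), error = function(e) {
      warnings <<- c(warnings, conditionMessage(e)); NULL
    }) else NULL
  unc <- tryCatch(uncertainty_region(curves$block2, curves$block3),
                  error = function(e) {
                    warnings <<- c(warnings, conditionMessage(e)); NULL
                  })

  tf <- features[features$run_index %in% test_runs, ]
  complete <- stats::complete.cases(tf[, c("distance_from_screen",
                                           "swim_activity",
                                           "directional_bias")])
  if (any(!complete))
    warnings <- c(warnings, sprintf("%d test-run rows with missing metrics dropped from DA",
                                    sum(!complete)))
  tfc <- tf[complete, ]
  da <- tryCatch(fisher_da(tfc[, c("distance_from_screen", "swim_activity",
                                   "directional_bias")], tfc$cue),
                 error = function(e) {
                   warnings <<- c(warnings, conditionMessage(e)); NULL
                 })

  second_level <- lapply(
    stats::setNames(nm = c("distance_from_screen", "swim_activity",
                           "directional_bias")),
    function(m) tryCatch(per_fish_second_level(tf, m),
                         error = function(e) NULL))

  # per-fish mean longest-trajectory direction, CF vs FM (rank-sum)
  agg <- stats::aggregate(longest_traj_direction ~ fish_id + cue,
                          data = tf, FUN = mean, na.rm = TRUE)
  lt_cf <- agg$longest_traj_direction[agg$cue == "NCF"]
  lt_fm <- agg$longest_traj_direction[agg$cue == "DFM"]
  traj_test <- tryCatch(wilcoxon_rank_sum(lt_cf, lt_fm),
                        error = function(e) NULL)

  act_cf <- frame_features$activity[frame_features$cue == "NCF"]
  act_fm <- frame_features$activity[frame_features$cue == "DFM"]
  bias_cf <- frame_features$bias[frame_features$cue == "NCF"]
  bias_fm <- frame_features$bias[frame_features$cue == "DFM"]
  stats_out <- list(
    da = da,
    second_level = second_level,
    longest_trajectory = list(
      test = traj_test,
      mean_direction_cf = mean(lt_cf, na.rm = TRUE),
      mean_direction_fm = mean(lt_fm, na.rm = TRUE)),
    activity_levene = tryCatch(levene_test(act_cf, act_fm),
                               error = function(e) NULL),
    activity_d = tryCatch(cohens_d(act_cf, act_fm), error = function(e) NA_real_),
    bias_d = tryCatch(cohens_d(bias_cf, bias_fm), error = function(e) NA_real_),
    discrimination_significant = !is.null(da) && da$p_value < 0.05)

  report <- structure(list(seed = seed, n_fish = n_fish,
                           test_runs = test_runs, features = features,
                           frame_features = frame_features, curves = curves,
                           zone = zone, uncertainty = unc, stats = stats_out,
                           warnings = warnings),
                      class = "run_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      features = file.path(out_dir, "features.csv"),
      frame_features = file.path(out_dir, "frame_features.csv"),
      proportion_block3 = file.path(out_dir, "proportion_block3.csv"),
      report = file.path(out_dir, "report.json"))
    utils::write.csv(features, paths$features, row.names = FALSE)
    utils::write.csv(frame_features, paths$frame_features, row.names = FALSE)
    utils::write.csv(as.data.frame(curves$block3), paths$proportion_block3,
                     row.names = FALSE)
    jsonlite::write_json(report_summary(report), paths$report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$paths <- paths
  }
  report
}

# flat, JSON-friendly summary of a run report
report_summary <- function(report) {
  da <- report$stats$da
  list(
    seed = report$seed, n_fish = report$n_fish,
    n_feature_rows = nrow(report$features),
    n_frame_rows = nrow(report$frame_features),
    wilks_lambda = if (!is.null(da)) da$wilks_lambda else NA,
    da_F = if (!is.null(da)) da$F_stat else NA,
    da_df1 = if (!is.null(da)) da$df1 else NA,
    da_df2 = if (!is.null(da)) da$df2 else NA,
    da_p = if (!is.null(da)) da$p_value else NA,
    da_auc = if (!is.null(da)) da$auc else NA,
    da_misclassification = if (!is.null(da)) da$misclassification_rate else NA,
    minus2_log_likelihood = if (!is.null(da)) da$minus2_log_likelihood else NA,
    discrimination_significant = report$stats$discrimination_significant,
    zone_lower = if (!is.null(report$zone) && report$zone$found)
      report$zone$lower else NA,
    zone_upper = if (!is.null(report$zone) && report$zone$found)
      report$zone$upper else NA,
    uncertainty_magnitude = if (!is.null(report$uncertainty))
      report$uncertainty$magnitude else NA,
    mean_traj_direction_cf = report$stats$longest_trajectory$mean_direction_cf,
    mean_traj_direction_fm = report$stats$longest_trajectory$mean_direction_fm,
    traj_rank_sum_p = if (!is.null(report$stats$longest_trajectory$test))
      report$stats$longest_trajectory$test$p_value else NA,
    bias_cohens_d = report$stats$bias_d,
    activity_cohens_d = report$stats$activity_d,
    warnings = report$warnings)
}

#' @export
print.run_report <- function(x, ...) {
  s <- report_summary(x)
  cat(sprintf("<run_report: %d fish, seed %d>\n", x$n_fish, x$seed))
  cat(sprintf("  DA: Wilks' lambda = %.4f, F(%d, %d) = %.3f, p = %.4g (%s)\n",
              s$wilks_lambda, s$da_df1, s$da_df2, s$da_F, s$da_p,
              if (isTRUE(s$discrimination_significant)) "significant"
              else "not significant"))
  if (!is.na(s$zone_lower))
    cat(sprintf("  decision zone: [%.0f, %.0f] mm\n", s$zone_lower, s$zone_upper))
  cat(sprintf("  mean longest-trajectory direction: CF %+.3f, FM %+.3f\n",
              s$mean_traj_direction_cf, s$mean_traj_direction_fm))
  invisible(x)
}

#' Write small deterministic fixtures
#'
#' Generates the plain-text fixtures used by tests and examples: a 3-row
#' pixel-frame tracking table, one simulated single-fish session (CSV), both
#' stimulus WAVs, and frames drawn so that their cue-conditional densities
#' follow a logistic proportion curve.
#'
#' @param out_dir Writable output directory.
#' @param seed Integer seed.
#' @return Invisibly, the manifest: a named character vector of file paths.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- experiment_config()
  paths <- c(
    tracking3 = file.path(out_dir, "tracking_3row_px.csv"),
    session = file.path(out_dir, "session_fish01.csv"),
    ncf = file.path(out_dir, "ncf.wav"),
    dfm = file.path(out_dir, "dfm.wav"),
    logistic = file.path(out_dir, "logistic_frames.csv"))
  # 3-row pixel-frame table, screen on the high-pixel side at x = 600
  utils::write.csv(data.frame(
    frame = 0:2, HeadX = c(600, 500, 350), HeadY = c(100, 120, 140),
    TailX = c(620, 520, 370), TailY = c(100, 120, 140),
    BodyAngle = c(pi, pi, pi)), paths["tracking3"], row.names = FALSE)
  tl <- build_timeline(cfg, seed = seed)
  ses <- simulate_session(fish_policy(), tl, cfg$tank, fps = cfg$fps,
                          seed = seed, fish_id = "fish01")
  write_tracking(ses$frames, paths["session"])
  write_wav(synthesize_ncf(stimulus_spec("NCF"), seed = seed), paths["ncf"])
  write_wav(synthesize_dfm(stimulus_spec("DFM")), paths["dfm"])
  lf <- logistic_frames(n = 4000, center = 100, scale = 20, seed = seed)
  utils::write.csv(lf, paths["logistic"], row.names = FALSE)
  invisible(paths)
}

#' Frames whose cue proportions follow a logistic curve
#'
#' Draws distances uniformly over `range` and assigns each frame the NCF
#' label with probability `plogis((center - x) / scale)`, so the true
#' proportion-of-density curve is logistic with the stated center and scale
#' (NCF mass near the screen). Used as a zone-detection fixture.
#'
#' @param n Number of frames.
#' @param center,scale Logistic midpoint and scale, mm.
#' @param range Distance range, mm.
#' @param seed Integer seed.
#' @return A data.frame with `distance` and `cue`.
#' @export
logistic_frames <- function(n = 4000, center = 100, scale = 20,
                            range = c(20, 240), seed = 1L) {
  with_local_seed(seed, {
    x <- stats::runif(n, range[1], range[2])
    p <- stats::plogis((center - x) / scale)
    cue <- ifelse(stats::runif(n) < p, "NCF", "DFM")
    data.frame(distance = x, cue = cue)
  })
}
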