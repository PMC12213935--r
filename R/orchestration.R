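#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one declarative
#' object. A single global seed deterministically derives one seed per stage
#' (see [derive_stage_seeds()]), so the whole run — cohort, audio, sampling,
#' screening, folds, bootstrap — is reproducible from `seed` alone, and any
#' stage can be re-run in isolation.
#'
#' @param seed Global integer seed.
#' @param preset `NULL` for a rate-based synthetic cohort, or `"fig1"` for
#'   the fixed-composition cohort (2,230 attempts; 136 non-speech; 295
#'   invalid-strategy; 286 missing sleepiness; 1,513 analysis-ready).
#' @param cohort A [cohort_config()]; its `seed` is overridden by the derived
#'   cohort-stage seed.
#' @param threshold Speech-detection amplitude threshold.
#' @param min_duration_samples Onset run-length requirement (0 = first
#'   exceedance).
#' @param validation_fraction Manual-validation subsample fraction.
#' @param screening_cutoff Node-purity cutoff for association screening.
#' @param reset_alpha RESET significance level gating the GAM stage.
#' @param k Number of cross-validation folds.
#' @param floor,cap Class-balancing rule for training folds.
#' @param bootstrap_b Bootstrap iterations for fold CIs.
#' @param averaging Metric averaging mode (`"macro"`, `"weighted"`,
#'   `"binary-collapse"`).
#' @param num_trees Random-forest size (screening, selection, classifier).
#' @param out_dir Optional directory; when set, every intermediate artifact
#'   is written as CSV/JSON.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, preset = NULL,
                       cohort = cohort_config(sample_rate = 8000),
                       threshold = 0.3, min_duration_samples = 0L,
                       validation_fraction = 0.083,
                       screening_cutoff = 50, reset_alpha = 0.05,
                       k = 4, floor = 180, cap = 500, bootstrap_b = 1000,
                       averaging = "macro", num_trees = 500,
                       out_dir = NULL) {
  if (!is.null(preset) && !identical(preset, "fig1")) {
    abort_vrt("unknown preset (only 'fig1' is defined)", "config_error")
  }
  structure(list(seed = as.integer(seed),
                 stage_seeds = derive_stage_seeds(seed),
                 preset = preset, cohort = cohort,
                 threshold = threshold,
                 min_duration_samples = min_duration_samples,
                 validation_fraction = validation_fraction,
                 screening_cutoff = screening_cutoff,
                 reset_alpha = reset_alpha,
                 k = k, floor = floor, cap = cap,
                 bootstrap_b = bootstrap_b, averaging = averaging,
                 num_trees = num_trees, out_dir = out_dir),
            class = "run_config")
}

# stream-synthesize each attempt's waveform and detect its onset;
# memory-light: one recording alive at a time
extract_onsets_from_plan <- function(attempts, config) {
  sr <- config$cohort$sample_rate
  with_seed(config$stage_seeds[["audio"]], {
    rows <- vector("list", nrow(attempts))
    for (i in seq_len(nrow(attempts))) {
      lat <- attempts$latency_s[i]
      dur <- if (is.na(lat)) 1.5 else lat + 0.5
      rec <- synthesize_recording(lat, dur, sample_rate = sr,
                                  source_id = attempts$source_id[i])
      rows[[i]] <- detect_onset(select_channel(rec, 1L), config$threshold,
                                config$min_duration_samples)
    }
    dplyr::bind_rows(rows)
  })
}

#' Run the full pipeline
#'
#' Executes the stages in study order: synthesize the cohort and its audio,
#' extract VRT by amplitude-threshold onset detection, run the
#' manual-validation workflow (ground-truth labels from the generator stand
#' in for the human annotator), assemble the analysis table through the
#' exclusion cascade, produce descriptive summaries and sex-difference
#' tests, run the association cascade (screening, linear model, RESET, GAM
#' when RESET rejects, AIC/ANOVA comparison), and fit the patient-level
#' stratified cross-validated random forest. With `out_dir` set in the
#' config, all intermediate artifacts are persisted as CSV/JSON.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: `flow`, `validation`, `observations`,
#'   `summary`, `sex_tests`, `association`, `prediction`,
#'   `aggregate_metrics`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort_seed <- config$stage_seeds[["cohort"]]

  if (identical(config$preset, "fig1")) {
    fx <- fig1_cohort(seed = cohort_seed, config = config$cohort)
    attempts <- fx$attempts
    participants <- fx$participants
    onsets <- extract_onsets_from_plan(attempts, config)
    flags <- tibble::tibble(
      non_speech = !onsets$is_speech[match(attempts$source_id, onsets$source_id)],
      invalid_strategy = attempts$invalid_strategy,
      missing_sleepiness = attempts$missing_sleepiness)
    flow <- account_flow(flags)
    truth_labels <- tibble::tibble(source_id = attempts$source_id,
                                   manual_speech = !attempts$non_speech)
    validation <- validate_speech_calls(onsets, truth_labels,
                                        fraction = config$validation_fraction,
                                        seed = config$stage_seeds[["validation"]])
    surv <- attr(flow, "survivors")
    obs <- attempts[surv, ]
    obs$vrt_seconds <- onsets$vrt_seconds[match(obs$source_id, onsets$source_id)]
    obs <- dplyr::left_join(
      obs, participants[, c("participant_id", "age", "sex", "race",
                            "education", "bzra_use")],
      by = "participant_id")
    observations <- tibble::as_tibble(obs[, c(
      "source_id", "participant_id", "week", "session_day", "test_type",
      "attempt_index", "vrt_seconds", "sleepiness", "mood", "cognition_scale",
      "caffeine", "alcohol", "age", "sex", "race", "education", "bzra_use",
      "difficulty", "pass_fail")])
    exclusions <- tibble::tibble(
      source_id = attempts$source_id[-surv],
      reason = c("non_speech", "invalid_strategy",
                 "missing_sleepiness")[max.col(cbind(
                   flags$non_speech[-surv],
                   !flags$non_speech[-surv] & flags$invalid_strategy[-surv],
                   !flags$non_speech[-surv] & !flags$invalid_strategy[-surv] &
                     flags$missing_sleepiness[-surv]), "first")])
  } else {
    cfg <- config$cohort
    cfg$seed <- cohort_seed
    tabs <- generate_cohort(cfg)
    participants <- tabs$participants
    onsets <- extract_onsets_from_plan(tabs$sessions, config)
    truth_labels <- tibble::tibble(source_id = tabs$sessions$source_id,
                                   manual_speech = !tabs$sessions$non_speech)
    validation <- validate_speech_calls(onsets, truth_labels,
                                        fraction = config$validation_fraction,
                                        seed = config$stage_seeds[["validation"]])
    assembled <- assemble(validation$corrected_results, tabs$ema,
                          tabs$sessions, participants)
    observations <- assembled$observations
    exclusions <- assembled$exclusions
    joined <- dplyr::left_join(
      dplyr::inner_join(tabs$sessions, validation$corrected_results,
                        by = "source_id"),
      tabs$ema, by = c("participant_id", "session_day"))
    flags <- tibble::tibble(non_speech = !joined$is_speech,
                            invalid_strategy = joined$invalid_strategy,
                            missing_sleepiness = is.na(joined$sleepiness))
    flow <- account_flow(flags)
  }

  summary <- summarize_cohort(observations)
  sex_tests <- sex_difference_tests(observations)
  association <- run_association(observations,
                                 cutoff = config$screening_cutoff,
                                 reset_alpha = config$reset_alpha,
                                 seed = config$stage_seeds[["association"]])
  plan <- plan_folds(observations, k = config$k,
                     seed = config$stage_seeds[["prediction"]])
  sel <- select_features_per_fold(observations, plan, cutoff = 20,
                                  num_trees = config$num_trees,
                                  seed = config$stage_seeds[["prediction"]])
  pred_features <- setdiff(sel$retained, "race")
  skcv <- run_skcv(observations, plan,
                   rule = balancing_rule(config$floor, config$cap,
                                         config$stage_seeds[["prediction"]]),
                   features = pred_features,
                   num_trees = config$num_trees,
                   bootstrap_b = config$bootstrap_b,
                   averaging = config$averaging,
                   seed = config$stage_seeds[["prediction"]])
  agg <- aggregate_folds(skcv$fold_metrics)

  report <- structure(list(flow = flow, validation = validation,
                           observations = observations,
                           exclusions = exclusions,
                           summary = summary, sex_tests = sex_tests,
                           association = association,
                           fold_plan = plan,
                           feature_selection = sel,
                           prediction = skcv,
                           aggregate_metrics = agg,
                           config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report_artifacts(report, config$out_dir)
  report
}

# persist every intermediate artifact as plain CSV/JSON
write_report_artifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  j <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           pretty = TRUE)
  w(as.data.frame(report$flow), "flow_ledger.csv")
  writeLines(format_flow(report$flow), file.path(dir, "flow_ledger.txt"))
  w(report$observations, "analysis_table.csv")
  w(report$exclusions, "exclusion_log.csv")
  j(unclass(report$summary), "cohort_summary.json")
  w(sleepiness_by_week(report$observations), "sleepiness_by_week.csv")
  w(report$association$linear$terms, "lr_terms.csv")
  if (!is.null(report$association$gam)) {
    curves <- report$association$gam$curves
    w(dplyr::bind_rows(lapply(names(curves), function(f) {
      cbind(term = f, curves[[f]])
    })), "gam_smooths.csv")
    j(list(smooth_terms = report$association$gam$smooth_terms,
           linear_terms = report$association$gam$linear_terms,
           aic = report$association$gam$aic,
           deviance_explained = report$association$gam$deviance_explained),
      "gam_summary.json")
    j(unclass(report$association$comparison), "model_comparison.json")
  }
  w(report$prediction$fold_metrics, "fold_metrics.csv")
  w(report$prediction$ledgers, "balancing_ledger.csv")
  j(lapply(report$fold_plan$folds, function(f) f), "fold_plan.json")
  j(stats::setNames(as.list(report$aggregate_metrics$mean),
                    report$aggregate_metrics$metric), "aggregate_metrics.json")
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== voice-based sleepiness pipeline report ==\n")
  cat(format_flow(x$flow), "\n")
  cat(sprintf("validation: n = %d, PPV %s, NPV %s\n",
              x$validation$subsample_size,
              format(round_half_up(100 * x$validation$ppv, 1)),
              format(round_half_up(100 * x$validation$npv, 1))))
  cat(sprintf("VRT: median %.2f s, mean %.2f s (n = %d)\n",
              x$summary$vrt$median, x$summary$vrt$mean, x$summary$n_observations))
  cat(sprintf("linear model R^2 = %.3f, RESET p = %.3g\n",
              x$association$linear$r_squared, x$association$reset_p))
  if (!is.null(x$association$comparison)) {
    cat(sprintf("AIC: linear %.2f vs GAM %.2f (delta %.2f, ANOVA p = %.3g)\n",
                x$association$comparison$aic_linear,
                x$association$comparison$aic_gam,
                x$association$comparison$delta_aic,
                x$association$comparison$anova_p))
  }
  agg <- x$aggregate_metrics
  cat(sprintf("SKCV/RF (%s): %s\n", x$config$averaging,
              paste(sprintf("%s %.2f +/- %.2f", agg$metric,
                            round_half_up(agg$mean, 2),
                            round_half_up(agg$sd, 2)), collapse = ", ")))
  invisible(x)
}
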