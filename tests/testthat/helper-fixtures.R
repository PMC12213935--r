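# shared fixtures, all generated in code at test time

# observation table straight from the generator (planted latency stands in
# for detected VRT, so no audio synthesis is needed)
cohort_observations <- function(config) {
  tabs <- generate_cohort(config)
  onsets <- tibble::tibble(source_id = tabs$sessions$source_id,
                           is_speech = !tabs$sessions$non_speech,
                           vrt_seconds = tabs$sessions$latency_s)
  assemble(onsets, tabs$ema, tabs$sessions, tabs$participants)$observations
}

# compact cohort for model-level tests: ~600-900 usable rows, quick folds
small_obs <- function(seed = 1, slope = NULL, n_participants = 12,
                      attempts = 16) {
  link <- if (is.null(slope)) vrt_link() else
    vrt_link(slope_per_level = slope)
  cohort_observations(cohort_config(
    n_participants = n_participants, attempts_per_session = attempts,
    nonspeech_rate = 0.05, invalid_strategy_rate = 0.08,
    missing_sleepiness_rate = 0.08, vrt_link = link, seed = seed))
}

# regression fixture with a known linear data-generating process
linear_truth_data <- function(n, seed, noise_sd = 0.5) {
  withr::with_seed(seed, {
    d <- data.frame(x1 = rnorm(n), x2 = runif(n, -2, 2), x3 = rnorm(n))
    d$y <- 1 + 0.8 * d$x1 - 0.5 * d$x2 + 0.3 * d$x3 + rnorm(n, 0, noise_sd)
    d
  })
}

# naive first-exceedance scan: the independent onset oracle
naive_onset_scan <- function(x, threshold, min_duration = 0L) {
  need <- max(1L, min_duration)
  for (i in seq_along(x)) {
    if (abs(x[i]) > threshold) {
      run <- 0L
      j <- i
      while (j <= length(x) && abs(x[j]) >= threshold) {
        run <- run + 1L
        j <- j + 1L
      }
      if (run >= need) return(i)
    }
  }
  NA_integer_
}
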