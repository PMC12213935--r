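#' Lognormal sleepiness-to-latency link parameters
#'
#' The generative coupling between the EMA sleepiness level and verbal
#' reaction time is lognormal:
#' `latency = exp(baseline_log_latency + slope_per_level * (sleepiness - 1) + e)`,
#' `e ~ N(0, noise_sd^2)`. The defaults were calibrated once, numerically, so
#' that under the default sleepiness distribution (23.7/39.5/17.1/19.8% for
#' levels 1-4) the marginal VRT has median 1.68 s, mean 2.19 s and SD 1.80 s.
#'
#' @param baseline_log_latency Log-seconds intercept (sleepiness level 1).
#' @param slope_per_level Log-seconds increase per sleepiness level.
#' @param noise_sd SD of the log-latency noise.
#' @return A `vrt_link` list.
#' @export
vrt_link <- function(baseline_log_latency = 0.106154,
                     slope_per_level = 0.314829,
                     noise_sd = 0.636527) {
  stopifnot(noise_sd >= 0)
  structure(list(baseline_log_latency = baseline_log_latency,
                 slope_per_level = slope_per_level,
                 noise_sd = noise_sd),
            class = "vrt_link")
}

#' Synthetic cohort configuration
#'
#' Declarative configuration for [generate_cohort()]. Defaults emulate the
#' study conditions: 16 participants aged 55+, weekly verbal paired-associates
#' (VPA) sessions on days 1/8/15/22 (optionally a fifth week), EMA sleepiness
#' distributed 23.7/39.5/17.1/19.8% over levels 1-4, ~6.1% non-speech
#' recordings, 14% invalid-strategy sessions, 12.8% missing sleepiness, and a
#' lognormal sleepiness-to-latency link reproducing the observed marginal VRT
#' summaries (median 1.68 s, mean 2.19 s).
#'
#' @param n_participants Number of participants.
#' @param n_weeks Maximum number of weekly sessions (4 or 5).
#' @param attempts_per_session Recorded attempts per session.
#' @param sleepiness_probs Probability vector over sleepiness levels 1-4.
#'   The default renormalizes the observed percentages (23.7/39.5/17.1/19.8,
#'   which sum to 100.1 after rounding) to an exact probability vector.
#' @param nonspeech_rate Proportion of attempts whose recording contains no
#'   speech.
#' @param invalid_strategy_rate Session-level probability of a self-reported
#'   invalid recall strategy (the flag is shared by all attempts in the
#'   session).
#' @param missing_sleepiness_rate Day-level probability that the EMA
#'   sleepiness item is missing.
#' @param vrt_link A [vrt_link()] object.
#' @param covariate_effects Named numeric vector of shifts applied to the
#'   latent sleepiness scale (logit of the cumulative distribution) per unit
#'   of the named standardized covariate; empty by default so that marginal
#'   sleepiness follows `sleepiness_probs` exactly.
#' @param participant_intercept_sd SD of a per-participant random intercept on
#'   latent sleepiness (0 by default: the downstream models ignore nesting).
#' @param latency_intercept_sd SD of a per-participant random intercept on
#'   log-latency (0 by default).
#' @param week5_prob Probability that a participant has a fifth weekly
#'   session.
#' @param caffeine_mean Poisson mean of daily caffeinated drinks.
#' @param sample_rate Audio sampling rate in Hz.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A validated `cohort_config` list.
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 4, seed = 1)
#' tabs <- generate_cohort(cfg)
#' names(tabs)
cohort_config <- function(n_participants = 16,
                          n_weeks = 5,
                          attempts_per_session = 33,
                          sleepiness_probs = c(0.237, 0.395, 0.171, 0.198) / 1.001,
                          nonspeech_rate = 0.061,
                          invalid_strategy_rate = 0.14,
                          missing_sleepiness_rate = 0.128,
                          vrt_link = vrtsleep::vrt_link(),
                          covariate_effects = numeric(0),
                          participant_intercept_sd = 0,
                          latency_intercept_sd = 0,
                          week5_prob = 0.2,
                          caffeine_mean = 1.5,
                          sample_rate = 16000,
                          seed = 1L) {
  if (length(sleepiness_probs) != 4 || any(sleepiness_probs < 0) ||
      abs(sum(sleepiness_probs) - 1) > 1e-9) {
    abort_vrt("sleepiness_probs must be 4 nonnegative values summing to 1",
              "config_error")
  }
  rates <- c(nonspeech_rate = nonspeech_rate,
             invalid_strategy_rate = invalid_strategy_rate,
             missing_sleepiness_rate = missing_sleepiness_rate,
             week5_prob = week5_prob)
  bad <- names(rates)[rates < 0 | rates > 1]
  if (length(bad)) {
    abort_vrt(paste0("rates must lie in [0, 1]: ", paste(bad, collapse = ", ")),
              "config_error")
  }
  if (n_participants < 0 || sample_rate <= 0 || attempts_per_session < 1 ||
      !n_weeks %in% c(4, 5)) {
    abort_vrt("need n_participants >= 0, sample_rate > 0, attempts_per_session >= 1, n_weeks in {4, 5}",
              "config_error")
  }
  structure(list(n_participants = as.integer(n_participants),
                 n_weeks = as.integer(n_weeks),
                 attempts_per_session = as.integer(attempts_per_session),
                 sleepiness_probs = sleepiness_probs,
                 nonspeech_rate = nonspeech_rate,
                 invalid_strategy_rate = invalid_strategy_rate,
                 missing_sleepiness_rate = missing_sleepiness_rate,
                 vrt_link = vrt_link,
                 covariate_effects = covariate_effects,
                 participant_intercept_sd = participant_intercept_sd,
                 latency_intercept_sd = latency_intercept_sd,
                 week5_prob = week5_prob,
                 caffeine_mean = caffeine_mean,
                 sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw ordinal sleepiness from base probabilities shifted on the latent
# (cumulative-logit) scale; shift 0 reproduces `probs` exactly.
draw_sleepiness <- function(n, probs, shift = 0) {
  if (n == 0L) return(integer(0))
  cum <- cumsum(probs)[1:3]
  cum <- pmin(pmax(cum, 1e-12), 1 - 1e-12)
  shift <- rep_len(shift, n)
  thr <- stats::qlogis(matrix(cum, n, 3, byrow = TRUE)) - shift
  u <- stats::qlogis(stats::runif(n))
  1L + rowSums(u > thr)
}

#' Draw verbal reaction times for sleepiness levels
#'
#' Applies the lognormal link: latencies are
#' `exp(b0 + slope * (sleepiness - 1) + N(0, sd))`, strictly positive, and
#' nondecreasing in sleepiness in expectation whenever the slope is
#' nonnegative. Uses the current RNG stream; seed in the caller for
#' reproducibility.
#'
#' @param sleepiness Integer vector of sleepiness levels 1-4 (no missing).
#' @param link A [vrt_link()] object.
#' @param intercept Optional per-observation additive shift on the log scale
#'   (e.g. a participant random intercept); recycled.
#' @return Numeric vector of latencies in seconds.
#' @export
#' @examples
#' set.seed(1)
#' latency_for(c(1, 4), vrt_link(noise_sd = 0))
latency_for <- function(sleepiness, link = vrt_link(), intercept = 0) {
  stopifnot(!anyNA(sleepiness), all(sleepiness %in% 1:4))
  n <- length(sleepiness)
  exp(link$baseline_log_latency + link$slope_per_level * (sleepiness - 1) +
        rep_len(intercept, n) + stats::rnorm(n, 0, link$noise_sd))
}

#' Generate a synthetic cohort
#'
#' Produces three keyed tables — participants, daily EMA records on test days,
#' and the per-attempt session plan — whose statistical structure matches the
#' configured study conditions. The output is a deterministic function of the
#' configuration (including its seed).
#'
#' The session table carries the generative ground truth for each attempt:
#' the planted speech-onset latency (`latency_s`, `NA` for non-speech
#' attempts) and the `non_speech` flag, so downstream onset detection can be
#' validated against known truth.
#'
#' @param config A [cohort_config()].
#' @return A list of tibbles: `participants`, `ema`, `sessions`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  empty <- function() list(
    participants = tibble::tibble(participant_id = character(0), age = numeric(0),
      sex = character(0), race = character(0), education = numeric(0),
      bzra_use = logical(0), mmse = integer(0)),
    ema = tibble::tibble(participant_id = character(0), session_day = integer(0),
      sleepiness = integer(0), mood = integer(0), cognition_scale = integer(0),
      caffeine = integer(0), alcohol = logical(0), tobacco = logical(0)),
    sessions = tibble::tibble(participant_id = character(0), week = integer(0),
      session_day = integer(0), test_type = character(0), attempt_index = integer(0),
      source_id = character(0), difficulty = numeric(0), invalid_strategy = logical(0),
      pass_fail = logical(0), non_speech = logical(0), latency_s = numeric(0)))
  if (config$n_participants == 0L) return(empty())
  with_seed(config$seed, {
    np <- config$n_participants
    ids <- sprintf("P%02d", seq_len(np))
    participants <- tibble::tibble(
      participant_id = ids,
      age = pmin(pmax(stats::rnorm(np, 66.34, 5.1), 55), 80),
      # fixed composition (11/16 female; 14/1/1 race at n = 16), shuffled,
      # rather than i.i.d. draws: the cohort make-up is a study condition
      sex = sample(rep(c("female", "male"),
                       c(round(np * 11 / 16), np - round(np * 11 / 16)))),
      race = sample(c(rep("White", np - min(np - 1, 2)),
                      rep(c("Black or AA", "Hispanic or Latino"),
                          length.out = min(np - 1, 2)))),
      education = pmin(pmax(round(stats::rnorm(np, 16.5, 1.9)), 12), 20),
      bzra_use = stats::runif(np) < 0.5,
      mmse = sample(24:30, np, TRUE))
    slp_int <- stats::rnorm(np, 0, config$participant_intercept_sd)
    lat_int <- stats::rnorm(np, 0, config$latency_intercept_sd)
    names(slp_int) <- names(lat_int) <- ids

    weeks_per <- 4L + (config$n_weeks == 5L) * (stats::runif(np) < config$week5_prob)
    sess <- do.call(rbind, lapply(seq_len(np), function(i) {
      wk <- seq_len(weeks_per[i])
      expand.grid(participant_id = ids[i], week = wk,
                  attempt_index = seq_len(config$attempts_per_session),
                  stringsAsFactors = FALSE)
    }))
    sess <- tibble::as_tibble(sess[order(sess$participant_id, sess$week,
                                         sess$attempt_index), ])
    sess$session_day <- (sess$week - 1L) * 7L + 1L
    n_att <- nrow(sess)
    sess$test_type <- sample(c("VPA-I", "VPA-DR"), n_att, TRUE, prob = c(0.75, 0.25))
    sess$source_id <- sprintf("%s_w%d_a%02d", sess$participant_id, sess$week,
                              sess$attempt_index)
    sess$difficulty <- stats::rnorm(n_att)
    sess$pass_fail <- stats::runif(n_att) < 0.7

    # invalid strategy is a session-level self-report, shared across attempts
    skey <- paste(sess$participant_id, sess$week)
    usess <- unique(skey)
    invalid <- stats::setNames(stats::runif(length(usess)) < config$invalid_strategy_rate, usess)
    sess$invalid_strategy <- unname(invalid[skey])

    # day-level EMA; sleepiness shifted by optional participant intercept and
    # standardized covariate effects on the latent scale
    ema <- unique(sess[, c("participant_id", "session_day")])
    ne <- nrow(ema)
    ema$mood <- sample(1:4, ne, TRUE, prob = c(0.2, 0.4, 0.3, 0.1))
    ema$cognition_scale <- sample(1:4, ne, TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
    ema$caffeine <- stats::rpois(ne, config$caffeine_mean)
    ema$alcohol <- stats::runif(ne) < 0.2
    ema$tobacco <- stats::runif(ne) < 0.05
    shift <- slp_int[ema$participant_id]
    if (length(config$covariate_effects)) {
      covs <- ema
      covs$age <- participants$age[match(ema$participant_id, participants$participant_id)]
      for (nm in names(config$covariate_effects)) {
        if (!nm %in% names(covs)) next
        z <- as.numeric(covs[[nm]])
        z <- if (stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else z * 0
        shift <- shift + config$covariate_effects[[nm]] * z
      }
    }
    # one day-level draw is the truth; the EMA table reports it, masked at
    # the configured missingness rate, while latencies always use the truth
    truth <- draw_sleepiness(ne, config$sleepiness_probs, shift)
    ema$sleepiness <- truth
    ema$sleepiness[stats::runif(ne) < config$missing_sleepiness_rate] <- NA_integer_
    ema_key <- paste(ema$participant_id, ema$session_day)
    ema <- tibble::as_tibble(ema[, c("participant_id", "session_day", "sleepiness",
                                     "mood", "cognition_scale", "caffeine",
                                     "alcohol", "tobacco")])

    sk <- paste(sess$participant_id, sess$session_day)
    att_slp <- truth[match(sk, ema_key)]
    sess$non_speech <- stats::runif(n_att) < config$nonspeech_rate
    sess$latency_s <- latency_for(att_slp, config$vrt_link,
                                  lat_int[sess$participant_id])
    sess$latency_s[sess$non_speech] <- NA_real_
    list(participants = participants, ema = ema, sessions = sess)
  })
}

#' Synthesize one test-attempt recording
#'
#' Builds a PCM waveform with low-amplitude background noise and, for speech
#' attempts, a tonal speech burst starting exactly at the planted latency: all
#' samples before `round(latency_s * sample_rate)` (zero-based) have absolute
#' amplitude at most `noise_amplitude`, and the onset sample has absolute
#' amplitude `speech_amplitude`. With `latency_s = NA` the recording is pure
#' sub-threshold noise (a non-speech attempt). Stereo output carries the
#' signal on the left channel (channel 1); the right channel is noise only.
#'
#' @param latency_s Planted onset latency in seconds, or `NA` for non-speech.
#' @param duration_s Total duration in seconds (must exceed `latency_s`).
#' @param sample_rate Sampling rate in Hz.
#' @param speech_amplitude Burst amplitude as a fraction of full scale; must
#'   exceed the detection threshold in use.
#' @param noise_amplitude Background noise amplitude bound; must stay below
#'   the detection threshold.
#' @param n_channels 1 (mono) or 2 (stereo, speech left).
#' @param source_id Identifier carried through to detection results.
#' @return An [audio_recording()].
#' @export
#' @examples
#' set.seed(1)
#' rec <- synthesize_recording(0.5, 1, sample_rate = 8000)
#' detect_onset(select_channel(rec))$vrt_seconds
synthesize_recording <- function(latency_s, duration_s,
                                 sample_rate = 16000,
                                 speech_amplitude = 0.8,
                                 noise_amplitude = 0.05,
                                 n_channels = 2,
                                 source_id = NA_character_) {
  stopifnot(duration_s > 0, sample_rate > 0,
            speech_amplitude > noise_amplitude, n_channels %in% 1:2)
  if (!is.na(latency_s) && (latency_s < 0 || latency_s >= duration_s)) {
    abort_vrt("latency_s must satisfy 0 <= latency_s < duration_s",
              "argument_error")
  }
  n <- max(1L, round(duration_s * sample_rate))
  left <- stats::runif(n, -noise_amplitude, noise_amplitude)
  if (!is.na(latency_s)) {
    onset <- round(latency_s * sample_rate)   # zero-based onset sample
    idx <- (onset + 1L):n
    t_rel <- (idx - idx[1]) / sample_rate
    burst_len <- min(length(idx), round(0.5 * sample_rate))
    burst <- speech_amplitude * cos(2 * pi * 440 * t_rel)
    burst[-seq_len(burst_len)] <- burst[-seq_len(burst_len)] * 0.5
    left[idx] <- burst
  }
  samples <- if (n_channels == 2) {
    cbind(left, stats::runif(n, -noise_amplitude, noise_amplitude))
  } else {
    matrix(left, ncol = 1)
  }
  audio_recording(samples, sample_rate, bit_depth = 16, source_id = source_id)
}

#' Write cohort audio as WAV files with a manifest
#'
#' Renders every attempt in a session table to a 16-bit PCM WAV file and
#' writes `manifest.csv` mapping file path to session row.
#'
#' @param sessions Session table from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [cohort_config()] used (for the sample rate and seed).
#' @param margin_s Seconds of audio kept after the onset.
#' @param nonspeech_duration_s Duration of non-speech recordings.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort_audio <- function(sessions, dir, config,
                               margin_s = 0.75, nonspeech_duration_s = 1.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed + 1L, {
    paths <- character(nrow(sessions))
    for (i in seq_len(nrow(sessions))) {
      lat <- sessions$latency_s[i]
      dur <- if (is.na(lat)) nonspeech_duration_s else lat + margin_s
      rec <- synthesize_recording(lat, dur, sample_rate = config$sample_rate,
                                  source_id = sessions$source_id[i])
      paths[i] <- file.path(dir, paste0(sessions$source_id[i], ".wav"))
      write_wav(rec$samples, rec$sample_rate, paths[i], bit_depth = 16)
    }
    manifest <- tibble::tibble(path = paths, source_id = sessions$source_id)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    invisible(manifest)
  })
}

#' Attempt table reproducing the study's flow composition
#'
#' Builds a 2,230-attempt table in which exactly 136 attempts are non-speech,
#' 295 of the remaining speech attempts are invalid-strategy sessions, and 286
#' of the remaining attempts have missing sleepiness — so the exclusion
#' cascade ends at exactly 1,513 analysis-ready rows. Unlike
#' [generate_cohort()], whose flags are Bernoulli draws at the configured
#' rates, this preset assigns exact flag counts (sampled index sets), and
#' sleepiness missingness is applied at attempt level so the composition is
#' exact. Each surviving attempt carries an observed sleepiness level and a
#' planted latency from the configured link.
#'
#' @param seed Integer seed.
#' @param config A [cohort_config()]; sizes in the config are ignored (the
#'   composition is fixed), but the sleepiness distribution and VRT link are
#'   used.
#' @return A list with `attempts` (the flagged attempt table),
#'   `participants`, and `ema` (attempt-level, already joined fields).
#' @export
fig1_cohort <- function(seed = 1L, config = cohort_config(seed = seed)) {
  n_total <- 2230L; n_nonspeech <- 136L; n_invalid <- 295L; n_missing <- 286L
  base_cfg <- cohort_config(
    n_participants = 16, n_weeks = 5, attempts_per_session = 33,
    sleepiness_probs = config$sleepiness_probs,
    nonspeech_rate = 0, invalid_strategy_rate = 0, missing_sleepiness_rate = 0,
    vrt_link = config$vrt_link,
    participant_intercept_sd = config$participant_intercept_sd,
    week5_prob = 1, caffeine_mean = config$caffeine_mean,
    sample_rate = config$sample_rate, seed = as.integer(seed))
  tabs <- generate_cohort(base_cfg)
  att <- tabs$sessions
  if (nrow(att) < n_total) {
    abort_vrt("base cohort too small for the fixed composition", "config_error")
  }
  # drop the excess attempts uniformly at random so every participant keeps
  # sessions in the fixed-size table
  att <- with_seed(as.integer(seed) + 3L,
                   att[sort(sample(nrow(att), n_total)), ])
  ema_key <- paste(tabs$ema$participant_id, tabs$ema$session_day)
  att_key <- paste(att$participant_id, att$session_day)
  m <- match(att_key, ema_key)
  att$sleepiness <- tabs$ema$sleepiness[m]
  att$mood <- tabs$ema$mood[m]
  att$cognition_scale <- tabs$ema$cognition_scale[m]
  att$caffeine <- tabs$ema$caffeine[m]
  att$alcohol <- tabs$ema$alcohol[m]
  att$tobacco <- tabs$ema$tobacco[m]
  with_seed(as.integer(seed) + 7L, {
    idx <- seq_len(n_total)
    ns <- sample(idx, n_nonspeech)
    att$non_speech <- idx %in% ns
    pool <- setdiff(idx, ns)
    inv <- sample(pool, n_invalid)
    att$invalid_strategy <- idx %in% inv
    pool <- setdiff(pool, inv)
    mis <- sample(pool, n_missing)
    att$missing_sleepiness <- idx %in% mis
    att$sleepiness[att$missing_sleepiness] <- NA_integer_
    att$latency_s[att$non_speech] <- NA_real_
  })
  list(attempts = tibble::as_tibble(att),
       participants = tabs$participants,
       ema = tabs$ema)
}
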