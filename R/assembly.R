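#' Assemble the analysis dataset
#'
#' Joins per-recording onset results with the session plan, the day-level EMA
#' record (the EMA record on the same test day is used; if several exist for
#' a participant-day the last one wins, with a warning), and the participant
#' table, then routes rows through the exclusion cascade — non-speech
#' recordings, invalid-strategy sessions, missing sleepiness — into an
#' exclusion log. Every input onset row appears exactly once in the
#' observations or the log, and the survivor set equals the final stage of
#' [account_flow()] on the same flags.
#'
#' @param onsets Onset-result table (`source_id`, `is_speech`,
#'   `vrt_seconds`).
#' @param ema EMA table (`participant_id`, `session_day`, `sleepiness`,
#'   `mood`, `cognition_scale`, `caffeine`, `alcohol`, `tobacco`).
#' @param sessions Session plan (`source_id`, `participant_id`, `week`,
#'   `session_day`, `test_type`, `attempt_index`, `difficulty`,
#'   `invalid_strategy`, `pass_fail`).
#' @param participants Participant table (`participant_id`, `age`, `sex`,
#'   `race`, `education`, `bzra_use`).
#' @return A list: `observations` (analysis-ready rows), `exclusions`
#'   (`source_id`, `reason`).
#' @export
assemble <- function(onsets, ema, sessions, participants) {
  need <- function(tbl, cols, what) {
    miss <- setdiff(cols, names(tbl))
    if (length(miss)) {
      abort_vrt(paste0(what, " table missing column(s): ",
                       paste(miss, collapse = ", ")), "schema_error")
    }
  }
  need(onsets, c("source_id", "is_speech", "vrt_seconds"), "onsets")
  need(sessions, c("source_id", "participant_id", "week", "session_day",
                   "test_type", "attempt_index", "difficulty",
                   "invalid_strategy", "pass_fail"), "sessions")
  need(ema, c("participant_id", "session_day", "sleepiness", "mood",
              "cognition_scale", "caffeine", "alcohol"), "ema")
  need(participants, c("participant_id", "age", "sex", "race", "education",
                       "bzra_use"), "participants")

  dup <- duplicated(ema[, c("participant_id", "session_day")])
  if (any(dup)) {
    warning(sprintf("%d duplicate EMA record(s) for a participant-day; keeping the last",
                    sum(dup)))
    ema <- ema[!duplicated(ema[, c("participant_id", "session_day")],
                           fromLast = TRUE), ]
  }

  tbl <- dplyr::inner_join(sessions, onsets, by = "source_id")
  lost <- setdiff(onsets$source_id, tbl$source_id)
  tbl <- dplyr::left_join(tbl, ema, by = c("participant_id", "session_day"))
  known <- tbl$participant_id %in% participants$participant_id
  if (!all(known)) {
    abort_vrt(paste0("participant record missing for: ",
                     paste(unique(tbl$participant_id[!known]), collapse = ", ")),
              "schema_error")
  }
  tbl <- dplyr::left_join(
    tbl, participants[, c("participant_id", "age", "sex", "race",
                          "education", "bzra_use")],
    by = "participant_id")

  reason <- rep(NA_character_, nrow(tbl))
  reason[is.na(reason) & !tbl$is_speech] <- "non_speech"
  reason[is.na(reason) & tbl$invalid_strategy] <- "invalid_strategy"
  reason[is.na(reason) & is.na(tbl$sleepiness)] <- "missing_sleepiness"

  obs <- tbl[is.na(reason), ]
  obs <- tibble::as_tibble(obs[, c(
    "source_id", "participant_id", "week", "session_day", "test_type",
    "attempt_index", "vrt_seconds", "sleepiness", "mood", "cognition_scale",
    "caffeine", "alcohol", "age", "sex", "race", "education", "bzra_use",
    "difficulty", "pass_fail")])
  exclusions <- tibble::tibble(
    source_id = c(tbl$source_id[!is.na(reason)], lost),
    reason = c(reason[!is.na(reason)], rep("no_session_match", length(lost))))
  list(observations = obs, exclusions = exclusions)
}

iqr_bounds <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)

num_summary <- function(x) {
  q <- iqr_bounds(x)
  list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
       iqr_low = q[1], iqr_high = q[2], min = min(x), max = max(x))
}

#' Descriptive cohort summary
#'
#' Participant-level characteristics (age, sex, race, education; one row per
#' participant) plus observation-level sleepiness proportions and VRT
#' summaries. SDs use the n-1 denominator; medians and IQRs use linear
#' interpolation (quantile type 7); percentages are rounded half-up to one
#' decimal at presentation only.
#'
#' @param observations Assembled observation table.
#' @return A `cohort_summary` list.
#' @export
summarize_cohort <- function(observations) {
  if (nrow(observations) == 0) abort_vrt("empty table", "argument_error")
  ppl <- observations[!duplicated(observations$participant_id),
                      c("participant_id", "age", "sex", "race", "education")]
  pct <- function(n) round_half_up(100 * n / sum(n), 1)
  sex_n <- table(ppl$sex)
  race_n <- table(ppl$race)
  slp_n <- table(factor(observations$sleepiness, levels = 1:4))
  structure(list(
    n_participants = nrow(ppl),
    n_observations = nrow(observations),
    age = num_summary(ppl$age),
    sex = list(counts = as.list(sex_n), percents = as.list(pct(sex_n))),
    race = list(counts = as.list(race_n), percents = as.list(pct(race_n))),
    education = num_summary(ppl$education),
    sleepiness_percents = as.list(pct(slp_n)),
    vrt = num_summary(observations$vrt_seconds)),
    class = "cohort_summary")
}

#' Sleepiness-by-week wide table
#'
#' One row per participant, one column per session week, holding the modal
#' reported sleepiness level for that week (NA where no usable session
#' exists).
#'
#' @param observations Assembled observation table.
#' @return A wide tibble, participants by weeks.
#' @export
sleepiness_by_week <- function(observations) {
  agg <- stats::aggregate(sleepiness ~ participant_id + week,
                          data = observations,
                          FUN = function(v) {
                            tt <- table(v)
                            as.integer(names(tt)[which.max(tt)])
                          })
  wide <- stats::reshape(agg, idvar = "participant_id", timevar = "week",
                         direction = "wide")
  names(wide) <- sub("^sleepiness\\.", "week_", names(wide))
  tibble::as_tibble(wide[order(wide$participant_id), ])
}

#' Sex-difference tests on VRT
#'
#' Compares VRT between female and male observations with a Welch two-sample
#' t-test, a Mann-Whitney U test (normal approximation with tie correction),
#' and an F-test of the variance ratio (Levene's test via [car] is not used;
#' the classical F-test is the default, with `levene = TRUE` switching to a
#' median-centered Levene test).
#'
#' @param observations Assembled observation table with `vrt_seconds` and
#'   `sex`.
#' @param levene If `TRUE`, use a Brown-Forsythe (median-centered Levene)
#'   test for variances instead of the F-test.
#' @return A list of two-sided p-values: `t_test_p`, `mann_whitney_p`,
#'   `variance_test_p`.
#' @export
sex_difference_tests <- function(observations, levene = FALSE) {
  f <- observations$vrt_seconds[observations$sex == "female"]
  m <- observations$vrt_seconds[observations$sex == "male"]
  if (length(f) < 2 || length(m) < 2) {
    abort_vrt("need at least 2 observations per sex", "argument_error")
  }
  t_p <- if (stats::sd(c(f, m)) == 0) 1.0 else stats::t.test(f, m)$p.value
  w_p <- stats::wilcox.test(f, m, exact = FALSE, correct = FALSE)$p.value
  v_p <- if (levene) {
    g <- factor(rep(c("f", "m"), c(length(f), length(m))))
    z <- abs(c(f - stats::median(f), m - stats::median(m)))
    stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
  } else {
    stats::var.test(f, m)$p.value
  }
  list(t_test_p = t_p, mann_whitney_p = w_p, variance_test_p = v_p)
}
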