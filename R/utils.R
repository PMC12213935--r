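#' Round half away from zero
#'
#' Presentation rounding used for reported percentages and summary tables:
#' ties go away from zero (so 0.725 -> 0.73), unlike [base::round()]'s
#' round-half-even. Stored values are never rounded; this is applied only
#' when numbers are formatted for reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.725, 0.905), 2)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive per-stage seeds from one global seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived from
#' the single global seed by a fixed counter scheme:
#' `stage_seed = (seed mod 21474836) * 100 + stage_index`, with stages indexed
#' in pipeline order (cohort = 1, audio = 2, validation = 3, assembly = 4,
#' association = 5, prediction = 6, report = 7). This keeps every derived
#' seed inside the 32-bit integer range and lets any stage be re-run in
#' isolation with the same stream it saw inside the full pipeline.
#'
#' @param seed Integer global seed.
#' @return Named integer vector of stage seeds.
#' @export
#' @examples
#' derive_stage_seeds(1)
derive_stage_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  base <- as.integer(abs(seed) %% 21474836L) * 100L
  stages <- c("cohort", "audio", "validation", "assembly",
              "association", "prediction", "report")
  stats::setNames(base + seq_along(stages), stages)
}

# assert helper producing the error classes used across the package
abort_vrt <- function(message, class) {
  stop(structure(class = c(class, "vrtsleep_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
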