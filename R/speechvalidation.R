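#' 2x2 confusion matrix for speech classification
#'
#' The positive class is "speech" throughout: `tp` counts recordings
#' predicted speech that truly contain speech, `tn` predicted non-speech that
#' truly contain none.
#'
#' @param tp,fp,fn,tn Nonnegative counts.
#' @return A `confusion_matrix` object.
#' @export
#' @examples
#' confusion_metrics(confusion_matrix(35, 0, 14, 136))
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort_vrt("confusion counts must be nonnegative integers", "argument_error")
  }
  structure(lapply(as.list(counts), as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("speech confusion: TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Draw the manual-validation subsample
#'
#' Samples `round(fraction * N)` rows without replacement for manual
#' speech/non-speech annotation; deterministic given the seed. An optional
#' stratified mode draws the fraction within each predicted class.
#'
#' @param results Onset-result table (one row per recording).
#' @param fraction Fraction of rows to draw, in (0, 1].
#' @param seed Integer seed.
#' @param stratify_by Optional column name (e.g. `"is_speech"`) to stratify
#'   the draw on; `NULL` (default) draws a simple random sample.
#' @return A tibble subset of `results`.
#' @export
draw_validation_subsample <- function(results, fraction, seed,
                                      stratify_by = NULL) {
  if (nrow(results) == 0) abort_vrt("results table is empty", "argument_error")
  if (fraction <= 0 || fraction > 1) {
    abort_vrt("fraction must lie in (0, 1]", "argument_error")
  }
  with_seed(seed, {
    if (is.null(stratify_by)) {
      size <- as.integer(round_half_up(fraction * nrow(results)))
      results[sort(sample(nrow(results), size)), ]
    } else {
      g <- results[[stratify_by]]
      keep <- unlist(lapply(split(seq_len(nrow(results)), g), function(ix) {
        sample(ix, as.integer(round_half_up(fraction * length(ix))))
      }))
      results[sort(keep), ]
    }
  })
}

#' Build a confusion matrix from aligned label vectors
#'
#' @param predicted Logical vector: algorithm's speech calls.
#' @param manual Logical vector: human annotations (truth).
#' @return A [confusion_matrix()].
#' @export
build_confusion <- function(predicted, manual) {
  if (length(predicted) != length(manual)) {
    abort_vrt("predicted and manual labels differ in length", "argument_error")
  }
  predicted <- as.logical(predicted); manual <- as.logical(manual)
  confusion_matrix(tp = sum(predicted & manual),
                   fp = sum(predicted & !manual),
                   fn = sum(!predicted & manual),
                   tn = sum(!predicted & !manual))
}

#' Predictive values and accuracy of the speech classifier
#'
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), accuracy = (TP+TN)/total, each
#' reported as `NA` (undefined), never 0, when its denominator is zero.
#'
#' @param cm A [confusion_matrix()].
#' @return A list with `ppv`, `npv`, `accuracy` (proportions in `[0, 1]`).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  list(
    ppv = if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_,
    npv = if (cm$tn + cm$fn > 0) cm$tn / (cm$tn + cm$fn) else NA_real_,
    accuracy = if (total > 0) (cm$tp + cm$tn) / total else NA_real_)
}

#' Relabel manually corrected recordings as speech
#'
#' The correction pass moves recordings that the threshold rule misclassified
#' as non-speech (but a human verified as speech) into the speech set. Every
#' id must exist and currently be non-speech, so re-applying the same
#' correction set errors rather than silently double-counting.
#'
#' @param results Onset-result table with `source_id` and `is_speech`.
#' @param corrections Character vector of `source_id`s to relabel as speech.
#' @return A list: `results` (corrected table), `speech_total`,
#'   `nonspeech_total`.
#' @export
apply_corrections <- function(results, corrections) {
  corrections <- unique(as.character(corrections))
  unknown <- setdiff(corrections, results$source_id)
  if (length(unknown)) {
    abort_vrt(paste0("unknown source_id(s): ", paste(unknown, collapse = ", ")),
              "validation_error")
  }
  hit <- results$source_id %in% corrections
  already <- results$source_id[hit & results$is_speech]
  if (length(already)) {
    abort_vrt(paste0("already labeled speech: ", paste(already, collapse = ", ")),
              "validation_error")
  }
  results$is_speech[hit] <- TRUE
  list(results = results,
       speech_total = sum(results$is_speech),
       nonspeech_total = sum(!results$is_speech))
}

#' Exclusion-cascade flow ledger
#'
#' Applies the exclusion stages in order — non-speech recordings, then
#' invalid-strategy sessions, then missing sleepiness — and records, for each
#' stage, how many records entered, were removed, and survived. Because each
#' flag is an independent property of a row, reordering stages changes the
#' per-stage removal counts but never the final survivor set.
#'
#' @param attempts Attempt table with logical columns named by `stages`.
#' @param stages Ordered character vector of flag columns; a `TRUE` flag
#'   removes the row at that stage.
#' @return A `flow_ledger` tibble: `stage`, `n_in`, `n_removed`, `n_out`.
#' @export
#' @examples
#' tbl <- tibble::tibble(non_speech = c(TRUE, FALSE, FALSE),
#'                       invalid_strategy = c(FALSE, TRUE, FALSE),
#'                       missing_sleepiness = FALSE)
#' account_flow(tbl)
account_flow <- function(attempts,
                         stages = c("non_speech", "invalid_strategy",
                                    "missing_sleepiness")) {
  missing_cols <- setdiff(stages, names(attempts))
  if (length(missing_cols)) {
    abort_vrt(paste0("missing flag column(s): ",
                     paste(missing_cols, collapse = ", ")), "schema_error")
  }
  alive <- rep(TRUE, nrow(attempts))
  rows <- lapply(stages, function(st) {
    flag <- as.logical(attempts[[st]])
    if (anyNA(flag)) abort_vrt(paste0("flag column has NA: ", st), "schema_error")
    n_in <- sum(alive)
    removed <- alive & flag
    alive <<- alive & !flag
    tibble::tibble(stage = st, n_in = n_in, n_removed = sum(removed),
                   n_out = sum(alive))
  })
  ledger <- dplyr::bind_rows(rows)
  attr(ledger, "survivors") <- which(alive)
  class(ledger) <- c("flow_ledger", class(ledger))
  ledger
}

#' Render a flow ledger as text
#'
#' @param ledger A [account_flow()] result.
#' @return A character scalar (multi-line flow diagram).
#' @export
format_flow <- function(ledger) {
  lines <- c(sprintf("records in: %d", ledger$n_in[1]),
             sprintf("  - %-20s removed %4d -> %4d remain",
                     ledger$stage, ledger$n_removed, ledger$n_out),
             sprintf("analysis-ready: %d", ledger$n_out[nrow(ledger)]))
  paste(lines, collapse = "\n")
}

#' Run the manual-validation workflow
#'
#' Draws the validation subsample, compares the algorithm's calls with manual
#' labels, computes PPV/NPV/accuracy, and applies the correction pass for
#' false negatives (manual speech predicted as non-speech) to the full table.
#'
#' @param results Onset-result table with `source_id` and `is_speech`.
#' @param manual_labels Tibble with `source_id` and logical `manual_speech`
#'   covering at least the drawn subsample.
#' @param fraction Subsample fraction.
#' @param seed Integer seed for the draw.
#' @return A `validation_report` list: `subsample_size`,
#'   `subsample_fraction`, `cm`, `ppv`, `npv`, `accuracy`,
#'   `corrected_speech_total`, `corrected_nonspeech_total`,
#'   `corrected_results`.
#' @export
validate_speech_calls <- function(results, manual_labels, fraction = 0.083,
                                  seed = 1L) {
  sub <- draw_validation_subsample(results, fraction, seed)
  m <- match(sub$source_id, manual_labels$source_id)
  if (anyNA(m)) abort_vrt("manual labels missing for some sampled ids",
                          "validation_error")
  manual <- manual_labels$manual_speech[m]
  cm <- build_confusion(sub$is_speech, manual)
  met <- confusion_metrics(cm)
  fn_ids <- sub$source_id[!sub$is_speech & manual]
  corrected <- if (length(fn_ids)) {
    apply_corrections(results, fn_ids)
  } else {
    list(results = results, speech_total = sum(results$is_speech),
         nonspeech_total = sum(!results$is_speech))
  }
  structure(list(subsample_size = nrow(sub), subsample_fraction = fraction,
                 cm = cm, ppv = met$ppv, npv = met$npv,
                 accuracy = met$accuracy,
                 corrected_speech_total = corrected$speech_total,
                 corrected_nonspeech_total = corrected$nonspeech_total,
                 corrected_results = corrected$results),
            class = "validation_report")
}
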