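make_results <- function(n_speech, n_nonspeech) {
  tibble::tibble(
    source_id = sprintf("r%04d", seq_len(n_speech + n_nonspeech)),
    is_speech = rep(c(TRUE, FALSE), c(n_speech, n_nonspeech)),
    vrt_seconds = c(runif(n_speech, 0.2, 4), rep(NA_real_, n_nonspeech)))
}

test_that("validation subsample sizing and determinism", {
  res <- make_results(2080, 150)
  expect_identical(nrow(draw_validation_subsample(res, 1, 1)), 2230L)
  expect_identical(nrow(draw_validation_subsample(res, 0.083, 1)), 185L)
  a <- draw_validation_subsample(res, 0.083, 42)
  b <- draw_validation_subsample(res, 0.083, 42)
  expect_identical(a, b)
  c2 <- draw_validation_subsample(res, 0.083, 43)
  expect_false(identical(a$source_id, c2$source_id))
  # stratified mode draws the fraction within each predicted class
  s <- draw_validation_subsample(res, 0.1, 1, stratify_by = "is_speech")
  expect_identical(sum(s$is_speech), 208L)
  expect_identical(sum(!s$is_speech), 15L)
  expect_error(draw_validation_subsample(res[0, ], 0.1, 1),
               class = "argument_error")
})

test_that("confusion construction matches a brute-force tally", {
  expect_identical(unclass(build_confusion(rep(c(TRUE, FALSE), c(10, 5)),
                                           rep(c(TRUE, FALSE), c(10, 5)))),
                   unclass(confusion_matrix(10, 0, 0, 5)))
  expect_identical(unclass(build_confusion(rep(TRUE, 4), rep(FALSE, 4))),
                   unclass(confusion_matrix(0, 4, 0, 0)))
  set.seed(14)
  p <- runif(200) < 0.6
  m <- runif(200) < 0.5
  cm <- build_confusion(p, m)
  tally <- table(factor(p, c(TRUE, FALSE)), factor(m, c(TRUE, FALSE)))
  expect_identical(cm$tp, unname(tally["TRUE", "TRUE"]))
  expect_identical(cm$fp, unname(tally["TRUE", "FALSE"]))
  expect_identical(cm$fn, unname(tally["FALSE", "TRUE"]))
  expect_identical(cm$tn, unname(tally["FALSE", "FALSE"]))
  expect_error(build_confusion(TRUE, c(TRUE, FALSE)), class = "argument_error")
})

test_that("predictive values use exact rational arithmetic", {
  m <- confusion_metrics(confusion_matrix(35, 0, 14, 136))
  expect_identical(m$ppv, 1)
  expect_identical(m$npv, 136 / 150)
  expect_identical(m$accuracy, 171 / 185)
  perfect <- confusion_metrics(confusion_matrix(1, 0, 0, 1))
  expect_identical(unlist(perfect), c(ppv = 1, npv = 1, accuracy = 1))
  # zero denominators are undefined, not zero
  expect_true(is.na(confusion_metrics(confusion_matrix(0, 0, 2, 3))$ppv))
  expect_true(is.na(confusion_metrics(confusion_matrix(2, 3, 0, 0))$npv))
})

test_that("correction pass relabels exactly the listed recordings once", {
  set.seed(3)
  res <- make_results(2080, 150)
  ident <- apply_corrections(res, character(0))
  expect_identical(ident$results, res)

  fn_ids <- res$source_id[!res$is_speech][1:14]
  out <- apply_corrections(res, fn_ids)
  expect_identical(out$speech_total, 2094L)
  expect_identical(out$nonspeech_total, 136L)
  # untouched rows unchanged
  expect_identical(out$results$is_speech[!res$source_id %in% fn_ids],
                   res$is_speech[!res$source_id %in% fn_ids])
  # a second application must fail: the ids are no longer non-speech
  expect_error(apply_corrections(out$results, fn_ids),
               class = "validation_error")
  expect_error(apply_corrections(res, "nope"), class = "validation_error")
})

test_that("flow ledger chains, conserves, and matches set filtering", {
  allfalse <- tibble::tibble(non_speech = rep(FALSE, 100),
                             invalid_strategy = FALSE,
                             missing_sleepiness = FALSE)
  led <- account_flow(allfalse)
  expect_true(all(led$n_out == 100))

  set.seed(8)
  tbl <- tibble::tibble(non_speech = runif(500) < 0.1,
                        invalid_strategy = runif(500) < 0.15,
                        missing_sleepiness = runif(500) < 0.12)
  led <- account_flow(tbl)
  # conservation at every stage and chaining between stages
  expect_true(all(led$n_in == led$n_removed + led$n_out))
  expect_identical(led$n_in[-1], led$n_out[-nrow(led)])
  # brute-force sequential filtering gives the same counts and survivors
  s1 <- which(!tbl$non_speech)
  s2 <- s1[!tbl$invalid_strategy[s1]]
  s3 <- s2[!tbl$missing_sleepiness[s2]]
  expect_identical(led$n_out, c(length(s1), length(s2), length(s3)))
  expect_identical(attr(led, "survivors"), s3)
  # stage order changes per-stage removals, never the survivor set
  led2 <- account_flow(tbl, stages = c("missing_sleepiness",
                                       "invalid_strategy", "non_speech"))
  expect_identical(sort(attr(led2, "survivors")), s3)
  expect_false(identical(led2$n_removed, led$n_removed))

  expect_error(account_flow(tbl[, 1:2]), class = "schema_error")
  expect_match(format_flow(led), "analysis-ready")
})

test_that("the validation workflow wires subsample, confusion and corrections", {
  set.seed(12)
  res <- make_results(300, 40)
  truth <- tibble::tibble(source_id = res$source_id,
                          manual_speech = res$is_speech)
  # plant 6 false negatives: truly speech, predicted non-speech
  fn <- res$source_id[!res$is_speech][1:6]
  truth$manual_speech[truth$source_id %in% fn] <- TRUE
  rep <- validate_speech_calls(res, truth, fraction = 1, seed = 1)
  expect_identical(rep$cm$fn, 6L)
  expect_identical(rep$cm$fp, 0L)
  expect_identical(rep$ppv, 1)
  expect_identical(rep$corrected_speech_total, 306L)
  expect_identical(rep$corrected_nonspeech_total, 34L)
})
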