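#' Patient-level stratified fold plan
#'
#' Partitions participants (never observations) into k test folds so that
#' fold-level sleepiness distributions are as similar as greedy assignment
#' on each patient's modal sleepiness achieves: patients are processed in
#' seeded random order within modal class (largest patients first) and each
#' is assigned to the fold currently holding the fewest test patients of
#' that modal class (ties: fewest total test patients, then lowest fold id).
#' Train and test patient sets are disjoint within every fold and each
#' patient appears in exactly one test fold, so no patient's observations
#' can leak between training and testing.
#'
#' @param data Observation table with `participant_id` and the
#'   stratification column.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratify_on Column used for stratification (default sleepiness).
#' @return A `fold_plan` list: `k`, `seed`, `stratify_on`, `folds` (list of
#'   `fold_id`, `train_patients`, `test_patients`).
#' @export
plan_folds <- function(data, k = 4, seed = 1L, stratify_on = "sleepiness") {
  pts <- unique(data$participant_id)
  if (length(pts) < k) {
    abort_vrt(sprintf("need at least k = %d patients, got %d", k, length(pts)),
              "argument_error")
  }
  modal <- vapply(pts, function(p) {
    v <- data[[stratify_on]][data$participant_id == p]
    tt <- table(v)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  n_obs <- vapply(pts, function(p) sum(data$participant_id == p), integer(1))
  ord <- with_seed(seed, {
    jitter <- stats::runif(length(pts))
    order(modal, -n_obs, jitter)
  })
  assign_fold <- integer(length(pts))
  class_count <- matrix(0L, k, 4)
  total_count <- integer(k)
  for (i in ord) {
    cls <- modal[i]
    best <- order(class_count[, cls], total_count, seq_len(k))[1]
    assign_fold[i] <- best
    class_count[best, cls] <- class_count[best, cls] + 1L
    total_count[best] <- total_count[best] + 1L
  }
  folds <- lapply(seq_len(k), function(f) {
    list(fold_id = f,
         test_patients = sort(pts[assign_fold == f]),
         train_patients = sort(pts[assign_fold != f]))
  })
  structure(list(k = k, seed = seed, stratify_on = stratify_on, folds = folds),
            class = "fold_plan")
}

#' Class-balancing rule
#'
#' Training classes with fewer than `floor` observations are skipped
#' (removed from training entirely); classes with more than `cap` are
#' downsampled without replacement to `cap`. Test data are never touched.
#'
#' @param floor Minimum training-class size.
#' @param cap Maximum training-class size.
#' @param seed Integer seed for downsampling.
#' @return A `balancing_rule` list.
#' @export
balancing_rule <- function(floor = 180, cap = 500, seed = 1L) {
  if (floor > cap) abort_vrt("floor must not exceed cap", "argument_error")
  structure(list(floor = floor, cap = cap, seed = seed),
            class = "balancing_rule")
}

#' Balance a training set by class
#'
#' @param train Training observation rows.
#' @param rule A [balancing_rule()].
#' @param class_col Class column name.
#' @return A list: `data` (balanced rows, always a subset of the input) and
#'   `ledger` (per class: `class`, `n_original`, `action`, `n_kept`).
#' @export
balance_training <- function(train, rule = balancing_rule(),
                             class_col = "sleepiness") {
  if (!class_col %in% names(train)) {
    abort_vrt(paste0("missing class column: ", class_col), "schema_error")
  }
  cls <- train[[class_col]]
  keep <- with_seed(rule$seed, {
    unlist(lapply(sort(unique(cls)), function(cv) {
      ix <- which(cls == cv)
      if (length(ix) < rule$floor) integer(0)
      else if (length(ix) > rule$cap) sort(sample(ix, rule$cap))
      else ix
    }))
  })
  ledger <- dplyr::bind_rows(lapply(sort(unique(cls)), function(cv) {
    n <- sum(cls == cv)
    action <- if (n < rule$floor) "skipped"
              else if (n > rule$cap) "downsampled" else "kept"
    tibble::tibble(class = cv, n_original = n, action = action,
                   n_kept = as.integer(if (action == "skipped") 0L
                                       else min(n, rule$cap)))
  }))
  if (length(keep) == 0) {
    abort_vrt("training set empty after class balancing", "balancing_error")
  }
  list(data = train[sort(keep), ], ledger = ledger, index = sort(keep))
}

#' Per-fold feature selection with an all-folds rule
#'
#' Runs random-forest importance on every fold's training rows and removes a
#' feature only when its node-purity importance falls below the cutoff in
#' EVERY fold; a feature below the cutoff in some folds but not all is
#' retained.
#'
#' @param data Observation table.
#' @param plan A [plan_folds()] result.
#' @param candidates Candidate feature columns.
#' @param cutoff Node-purity cutoff (default 20).
#' @param num_trees Trees per forest.
#' @param seed Integer seed.
#' @param outcome Outcome column.
#' @return A list: `retained`, `removed`, `per_fold` (features-by-folds
#'   importance matrix).
#' @export
select_features_per_fold <- function(data, plan,
                                     candidates = c("vrt_seconds",
                                                    "cognition_scale", "mood",
                                                    "age", "sex", "caffeine",
                                                    "bzra_use", "education",
                                                    "difficulty", "pass_fail",
                                                    "alcohol"),
                                     cutoff = 20, num_trees = 500, seed = 1L,
                                     outcome = "sleepiness") {
  imp <- sapply(plan$folds, function(fold) {
    tr <- data[data$participant_id %in% fold$train_patients, ]
    scr <- screen_features(tr, outcome = outcome, candidates = candidates,
                           cutoff = cutoff, manual_exclusions = character(0),
                           num_trees = num_trees,
                           seed = seed + fold$fold_id)
    scr$importance[candidates]
  })
  rownames(imp) <- candidates
  below_everywhere <- rowSums(imp >= cutoff) == 0
  list(retained = candidates[!below_everywhere],
       removed = candidates[below_everywhere],
       per_fold = imp)
}

# multiclass / binary-collapsed precision, recall, F1, accuracy
classification_metrics <- function(truth, pred,
                                   averaging = c("macro", "weighted",
                                                 "binary-collapse"),
                                   positive_min_level = 2) {
  averaging <- match.arg(averaging)
  if (averaging == "binary-collapse") {
    t2 <- truth >= positive_min_level
    p2 <- pred >= positive_min_level
    tp <- sum(p2 & t2); fp <- sum(p2 & !t2); fn <- sum(!p2 & t2)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
      2 * prec * rec / (prec + rec)
    } else NA_real_
    return(c(accuracy = mean(p2 == t2), precision = prec, recall = rec, f1 = f1))
  }
  classes <- sort(unique(truth))
  per <- vapply(classes, function(cv) {
    tp <- sum(pred == cv & truth == cv)
    fp <- sum(pred == cv & truth != cv)
    fn <- sum(pred != cv & truth == cv)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1, sum(truth == cv))
  }, numeric(4))
  w <- if (averaging == "weighted") per[4, ] / sum(per[4, ]) else
    rep(1 / length(classes), length(classes))
  c(accuracy = mean(pred == truth),
    precision = sum(per[1, ] * w),
    recall = sum(per[2, ] * w),
    f1 = sum(per[3, ] * w))
}

#' Stratified cross-validated random-forest prediction of sleepiness
#'
#' For each fold of the plan: balances the training rows by class, trains a
#' random-forest classifier on the selected features, predicts the held-out
#' patients' rows, and computes accuracy, precision, recall and F1 under the
#' chosen averaging mode, with bootstrap percentile 95% CIs obtained by
#' resampling the test-set (label, prediction) pairs. Test rows are never
#' balanced or modified; test rows of classes skipped from training remain
#' and count against recall.
#'
#' The averaging mode is explicit because 4-level precision/recall/F1 are
#' not uniquely defined: `"macro"` averages per-class metrics, `"weighted"`
#' weights by class prevalence, and `"binary-collapse"` dichotomizes at
#' `positive_min_level` (sleepy vs not).
#'
#' @param data Observation table.
#' @param plan A [plan_folds()] result covering the table's patients.
#' @param rule A [balancing_rule()].
#' @param features Predictor columns.
#' @param num_trees Trees per forest.
#' @param bootstrap_b Bootstrap iterations for the CIs.
#' @param averaging Averaging mode (see above).
#' @param positive_min_level Positive-class cut for binary collapse.
#' @param seed Integer seed.
#' @param outcome Outcome column.
#' @return A list: `fold_metrics` (tibble: fold, n_test, metric, point
#'   estimate and CI bounds per metric), `ledgers` (per-fold balancing
#'   ledgers), `predictions` (per-fold truth/prediction tibble).
#' @export
run_skcv <- function(data, plan, rule = balancing_rule(),
                     features = c("vrt_seconds", "cognition_scale", "mood",
                                  "age", "sex", "caffeine", "bzra_use",
                                  "education", "difficulty"),
                     num_trees = 500, bootstrap_b = 1000,
                     averaging = "macro", positive_min_level = 2,
                     seed = 1L, outcome = "sleepiness") {
  miss <- setdiff(c(outcome, features, "participant_id"), names(data))
  if (length(miss)) {
    abort_vrt(paste0("missing column(s): ", paste(miss, collapse = ", ")),
              "schema_error")
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  # factor-code once on the full table so train and test share factor levels
  coded <- as.data.frame(code_covariates(data[, features]))
  rows <- list(); ledgers <- list(); preds_out <- list()
  for (fold in plan$folds) {
    overlap <- intersect(fold$train_patients, fold$test_patients)
    if (length(overlap)) {
      abort_vrt("patient leakage: train and test sets overlap", "leakage_error")
    }
    test <- data[data$participant_id %in% fold$test_patients, ]
    if (nrow(test) == 0) {
      warning(sprintf("fold %d has an empty test set; excluded", fold$fold_id))
      next
    }
    train_idx <- which(data$participant_id %in% fold$train_patients)
    train <- data[train_idx, ]
    bal <- balance_training(train, balancing_rule(rule$floor, rule$cap,
                                                  rule$seed + fold$fold_id),
                            class_col = outcome)
    ledgers[[length(ledgers) + 1L]] <-
      cbind(fold_id = fold$fold_id, bal$ledger)
    in_test <- data$participant_id %in% fold$test_patients
    x_tr <- coded[train_idx[bal$index], , drop = FALSE]
    y_tr <- factor(bal$data[[outcome]], levels = 1:4)
    x_te <- coded[in_test, , drop = FALSE]
    rf <- with_seed(seed + 13L * fold$fold_id,
                    randomForest::randomForest(x = x_tr, y = droplevels(y_tr),
                                               ntree = num_trees))
    pred <- as.integer(as.character(
      stats::predict(rf, newdata = x_te)))
    truth <- as.integer(test[[outcome]])
    pt <- classification_metrics(truth, pred, averaging, positive_min_level)
    ci <- with_seed(seed + 29L * fold$fold_id, {
      boot <- replicate(bootstrap_b, {
        ix <- sample.int(length(truth), replace = TRUE)
        classification_metrics(truth[ix], pred[ix], averaging,
                               positive_min_level)
      })
      apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
            na.rm = TRUE, names = FALSE)
    })
    row <- tibble::tibble(fold_id = fold$fold_id, n_test = nrow(test),
                          averaging = averaging)
    for (m in metric_names) {
      j <- match(m, metric_names)
      row[[m]] <- unname(pt[m])
      row[[paste0(m, "_ci_low")]] <- min(ci[1, j], pt[m], na.rm = TRUE)
      row[[paste0(m, "_ci_high")]] <- max(ci[2, j], pt[m], na.rm = TRUE)
    }
    rows[[length(rows) + 1L]] <- row
    preds_out[[length(preds_out) + 1L]] <-
      tibble::tibble(fold_id = fold$fold_id, truth = truth, prediction = pred)
  }
  list(fold_metrics = dplyr::bind_rows(rows),
       ledgers = dplyr::bind_rows(ledgers),
       predictions = dplyr::bind_rows(preds_out))
}

#' Aggregate fold metrics
#'
#' Arithmetic mean and sample SD (n-1 denominator) of each metric across
#' folds, the shape of a cross-validation summary row ("Mean +/- SD").
#'
#' @param fold_metrics Either the `fold_metrics` tibble from [run_skcv()] or
#'   a tibble/data.frame with columns `accuracy`, `precision`, `recall`,
#'   `f1`.
#' @return A tibble: `metric`, `mean`, `sd`.
#' @export
#' @examples
#' tab3 <- tibble::tibble(accuracy = c(0.76, 0.58, 0.56, 0.65),
#'                        precision = c(0.76, 0.70, 0.76, 0.68),
#'                        recall = c(1.00, 0.80, 0.79, 0.75),
#'                        f1 = c(0.90, 0.80, 0.80, 0.70))
#' aggregate_folds(tab3)
aggregate_folds <- function(fold_metrics) {
  if (nrow(fold_metrics) < 2) {
    abort_vrt("need at least 2 folds to aggregate", "aggregation_error")
  }
  metric_names <- c("accuracy", "precision", "recall", "f1")
  dplyr::bind_rows(lapply(metric_names, function(m) {
    v <- fold_metrics[[m]]
    tibble::tibble(metric = m, mean = mean(v), sd = stats::sd(v))
  }))
}
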