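test_that("fold plans partition patients without leakage", {
  obs <- small_obs(seed = 2, n_participants = 16, attempts = 6)
  plan <- plan_folds(obs, k = 4, seed = 1)
  test_sets <- lapply(plan$folds, `[[`, "test_patients")
  expect_identical(sort(unlist(test_sets)), sort(unique(obs$participant_id)))
  expect_identical(vapply(test_sets, length, integer(1)), rep(4L, 4))
  for (f in plan$folds) {
    expect_length(intersect(f$train_patients, f$test_patients), 0)
    expect_setequal(c(f$train_patients, f$test_patients),
                    unique(obs$participant_id))
  }

  tiny <- obs[obs$participant_id %in% unique(obs$participant_id)[1:4], ]
  p4 <- plan_folds(tiny, k = 4, seed = 1)
  expect_identical(vapply(p4$folds, function(f) length(f$test_patients),
                          integer(1)), rep(1L, 4))
  expect_error(plan_folds(tiny, k = 5, seed = 1), class = "argument_error")
})

test_that("stratified planning balances fold sleepiness at least as well as random", {
  obs <- small_obs(seed = 4, n_participants = 16, attempts = 6)
  pts <- unique(obs$participant_id)
  fold_dist <- function(test_sets) {
    d <- sapply(test_sets, function(ps) {
      tabulate(obs$sleepiness[obs$participant_id %in% ps], 4)
    })
    d <- sweep(d, 2, pmax(colSums(d), 1), "/")
    max(dist(t(d), method = "manhattan"))
  }
  strat <- vapply(1:30, function(s) {
    fold_dist(lapply(plan_folds(obs, 4, seed = s)$folds, `[[`, "test_patients"))
  }, numeric(1))
  rand <- vapply(1:30, function(s) {
    g <- withr::with_seed(s, sample(rep(1:4, length.out = length(pts))))
    fold_dist(split(pts, g))
  }, numeric(1))
  expect_lte(mean(strat), mean(rand))
})

test_that("class balancing applies the floor and cap rules exactly", {
  train <- tibble::tibble(
    sleepiness = rep(c(1L, 2L, 3L), c(100, 300, 700)),
    x = seq_len(1100))
  out <- balance_training(train, balancing_rule(180, 500, seed = 8))
  kept <- table(out$data$sleepiness)
  expect_identical(as.integer(kept[c("2", "3")]), c(300L, 500L))
  expect_false("1" %in% names(kept))
  expect_identical(out$ledger$action, c("skipped", "kept", "downsampled"))
  # ledger conservation per class
  expect_identical(out$ledger$n_original, c(100L, 300L, 700L))
  expect_identical(out$ledger$n_kept, c(0L, 300L, 500L))
  # balanced rows are a subset of the input (no synthesis), across seeds
  for (s in 1:5) {
    o <- balance_training(train, balancing_rule(180, 500, seed = s))
    expect_true(all(o$data$x %in% train$x))
    expect_false(any(duplicated(o$data$x)))
  }
  # all classes in range -> identity
  mid <- tibble::tibble(sleepiness = rep(1:2, c(200, 250)), x = 1:450)
  expect_identical(balance_training(mid, balancing_rule(180, 500, 1))$data, mid)
  expect_error(balance_training(train[1:50, ], balancing_rule(180, 500, 1)),
               class = "balancing_error")
})

test_that("per-fold selection removes only features weak in every fold", {
  rule <- function(per_fold, cutoff) rownames(per_fold)[rowSums(per_fold >= cutoff) == 0]
  imp <- rbind(x = c(5, 8, 3, 1), y = c(5, 25, 3, 1), z = c(40, 60, 55, 90))
  expect_identical(rule(imp, 20), "x")

  obs <- small_obs(seed = 11, n_participants = 12, attempts = 10)
  obs$pure_noise <- withr::with_seed(3, rnorm(nrow(obs)) * 1e-4)
  plan <- plan_folds(obs, 4, seed = 1)
  sel <- select_features_per_fold(obs, plan,
                                  candidates = c("vrt_seconds", "age",
                                                 "pure_noise"),
                                  cutoff = 20, num_trees = 150, seed = 1)
  expect_true("vrt_seconds" %in% sel$retained)
  expect_identical(dim(sel$per_fold), c(3L, 4L))
  expect_setequal(c(sel$retained, sel$removed),
                  c("vrt_seconds", "age", "pure_noise"))
})

test_that("classification metrics follow closed-form confusion arithmetic", {
  cm <- vrtsleep:::classification_metrics
  truth <- rep(1:4, c(10, 20, 5, 15))
  # perfect prediction: everything is 1 in every mode
  for (mode in c("macro", "weighted", "binary-collapse")) {
    m <- cm(truth, truth, mode)
    expect_equal(unname(m), rep(1, 4))
  }
  # binary collapse with all-positive predictions and prevalence 0.76
  truth2 <- rep(c(4L, 1L), c(76, 24))
  pred2 <- rep(4L, 100)
  m <- cm(truth2, pred2, "binary-collapse", positive_min_level = 2)
  expect_equal(unname(m["accuracy"]), 0.76)
  expect_equal(unname(m["precision"]), 0.76)
  expect_equal(unname(m["recall"]), 1)
  expect_equal(unname(m["f1"]), 2 * 0.76 / 1.76)
  # macro average equals the hand-computed per-class mean
  set.seed(5)
  t3 <- sample(1:3, 200, TRUE)
  p3 <- sample(1:3, 200, TRUE)
  per <- sapply(1:3, function(cv) {
    tp <- sum(p3 == cv & t3 == cv)
    prec <- tp / sum(p3 == cv)
    rec <- tp / sum(t3 == cv)
    c(prec, rec, 2 * prec * rec / (prec + rec))
  })
  m3 <- cm(t3, p3, "macro")
  expect_equal(unname(m3["precision"]), mean(per[1, ]))
  expect_equal(unname(m3["recall"]), mean(per[2, ]))
  expect_equal(unname(m3["f1"]), mean(per[3, ]))
})

test_that("cross-validated prediction is leak-free, bounded and deterministic", {
  obs <- small_obs(seed = 19, n_participants = 12, attempts = 12)
  plan <- plan_folds(obs, 4, seed = 2)
  rule <- balancing_rule(floor = 10, cap = 300, seed = 2)
  out <- run_skcv(obs, plan, rule, num_trees = 120, bootstrap_b = 120,
                  seed = 2)
  fm <- out$fold_metrics
  expect_identical(nrow(fm), 4L)
  for (m in c("accuracy", "precision", "recall", "f1")) {
    expect_true(all(fm[[m]] >= 0 & fm[[m]] <= 1))
    expect_true(all(fm[[paste0(m, "_ci_low")]] <= fm[[m]] + 1e-12))
    expect_true(all(fm[[paste0(m, "_ci_high")]] >= fm[[m]] - 1e-12))
  }
  # balancing ledger conservation within every fold
  led <- out$ledgers
  expect_true(all(led$n_kept <= led$n_original))
  expect_true(all((led$action == "skipped") == (led$n_kept == 0)))
  # deterministic given the seed
  out2 <- run_skcv(obs, plan, rule, num_trees = 120, bootstrap_b = 120,
                   seed = 2)
  expect_identical(fm, out2$fold_metrics)
  # predictions only ever cover test patients of the fold
  for (f in plan$folds) {
    n_pred <- sum(out$predictions$fold_id == f$fold_id)
    expect_identical(n_pred,
                     sum(obs$participant_id %in% f$test_patients))
  }
})

test_that("bootstrap percentile CIs cover a known agreement rate", {
  p_true <- 0.8
  n <- 200
  B <- 300
  cover <- withr::with_seed(123, {
    mean(replicate(400, {
      agree <- runif(n) < p_true
      boots <- replicate(B, mean(agree[sample.int(n, replace = TRUE)]))
      ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
      ci[1] <= p_true && p_true <= ci[2]
    }))
  })
  expect_gte(cover, 0.90)
})

test_that("fold aggregation matches hand-computed mean and SD", {
  tab <- tibble::tibble(accuracy = c(0.76, 0.58, 0.56, 0.65),
                        precision = c(0.76, 0.70, 0.76, 0.68),
                        recall = c(1.00, 0.80, 0.79, 0.75),
                        f1 = c(0.90, 0.80, 0.80, 0.70))
  agg <- aggregate_folds(tab)
  expect_equal(agg$mean, vapply(tab, mean, numeric(1)), ignore_attr = TRUE)
  expect_equal(agg$sd, vapply(tab, sd, numeric(1)), ignore_attr = TRUE)

  same <- tab[c(1, 1, 1), ]
  expect_equal(aggregate_folds(same)$sd, rep(0, 4))
  expect_error(aggregate_folds(tab[1, ]), class = "aggregation_error")
})
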