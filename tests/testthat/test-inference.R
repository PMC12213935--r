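test_that("importance screening ranks a perfect predictor first", {
  obs <- small_obs(seed = 6)
  obs$leak <- obs$sleepiness
  scr <- screen_features(obs, candidates = c("leak", "vrt_seconds", "age",
                                             "caffeine"),
                         manual_exclusions = character(0), num_trees = 200,
                         seed = 1)
  expect_identical(names(which.max(scr$importance)), "leak")
  # retained/dropped/excluded partition the candidate set
  scr2 <- screen_features(obs, cutoff = 50, num_trees = 200, seed = 1)
  expect_setequal(c(scr2$retained, scr2$dropped, scr2$manually_excluded),
                  c("vrt_seconds", "cognition_scale", "mood", "age", "sex",
                    "caffeine", "bzra_use", "education", "difficulty",
                    "pass_fail", "alcohol", "race"))
  expect_true(all(scr2$importance[scr2$retained] >= scr2$cutoff))
  expect_true(all(scr2$importance[scr2$dropped] < scr2$cutoff))
  expect_false("race" %in% names(scr2$importance))
  # deterministic given seed
  scr3 <- screen_features(obs, cutoff = 50, num_trees = 200, seed = 1)
  expect_identical(scr2$importance, scr3$importance)

  obs$flat <- 2L
  expect_error(screen_features(obs, outcome = "flat"),
               class = "screening_error")
})

test_that("planted signal out-ranks independent noise across seeds", {
  hits <- vapply(1:20, function(s) {
    obs <- small_obs(seed = s, n_participants = 8, attempts = 8)
    obs$noise <- withr::with_seed(1000 + s, rnorm(nrow(obs)))
    scr <- screen_features(obs, candidates = c("vrt_seconds", "noise"),
                           manual_exclusions = character(0),
                           num_trees = 150, seed = s)
    scr$importance["vrt_seconds"] > scr$importance["noise"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("OLS recovers a noiseless planted model to machine precision", {
  d <- linear_truth_data(400, seed = 9, noise_sd = 0)
  # the perfect-fit warning from summary.lm is the point of this fixture
  fit <- suppressWarnings(fit_linear(d, c("x1", "x2", "x3"), outcome = "y"))
  # normal-equations oracle
  X <- cbind(1, d$x1, d$x2, d$x3)
  beta <- solve(t(X) %*% X, t(X) %*% d$y)
  expect_lt(sqrt(mean((fit$terms$estimate - beta)^2)), 1e-8)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$aic, AIC(lm(y ~ x1 + x2 + x3, d)))
  # CI = estimate +/- 1.96 SE
  expect_equal(fit$terms$ci_high - fit$terms$estimate,
               qnorm(0.975) * fit$terms$se)

  dc <- d
  dc$y <- 5
  flat <- suppressWarnings(fit_linear(dc, c("x1", "x2", "x3"), outcome = "y"))
  expect_equal(unname(flat$terms$estimate[-1]), rep(0, 3))
  expect_identical(flat$r_squared, 0)

  dd <- d
  dd$x3 <- dd$x1
  expect_error(fit_linear(dd, c("x1", "x2", "x3"), outcome = "y"),
               class = "argument_error")
  dd$x3 <- 1
  expect_error(fit_linear(dd, c("x1", "x2", "x3"), outcome = "y"),
               class = "argument_error")
})

test_that("a variance-decomposition construction recovers its R-squared", {
  # signal variance v, noise variance chosen so var explained = 0.586
  withr::with_seed(15, {
    n <- 10000
    x <- rnorm(n)
    signal <- 0.9 * x
    noise_var <- var(signal) * (1 / 0.586 - 1)
    d <- data.frame(x1 = x, y = signal + rnorm(n, 0, sqrt(noise_var)))
  })
  fit <- fit_linear(d, "x1", outcome = "y")
  expect_lt(abs(fit$r_squared - 0.586), 0.02)
})

test_that("RESET equals a hand-built augmented-model F-test and has power", {
  d <- linear_truth_data(300, seed = 21, noise_sd = 0.4)
  fit <- fit_linear(d, c("x1", "x2", "x3"), outcome = "y")
  p_pkg <- reset_test(fit)
  # oracle: F-test of adding fitted^2 and fitted^3
  f0 <- lm(y ~ x1 + x2 + x3, d)
  d2 <- transform(d, f2 = fitted(f0)^2, f3 = fitted(f0)^3)
  f1 <- lm(y ~ x1 + x2 + x3 + f2 + f3, d2)
  p_manual <- anova(f0, f1)[["Pr(>F)"]][2]
  expect_equal(p_pkg, p_manual, tolerance = 1e-10)

  # strong quadratic truth is detected
  for (s in 1:5) {
    dq <- withr::with_seed(30 + s, {
      x <- rnorm(500)
      data.frame(x1 = x, y = x + x^2 + rnorm(500, 0, 0.5))
    })
    expect_lt(reset_test(fit_linear(dq, "x1", outcome = "y")), 0.05)
  }
})

test_that("GAM smooths shrink to linearity under a linear truth", {
  d <- linear_truth_data(800, seed = 40, noise_sd = 0.5)
  g <- fit_gam(d, smooth_features = c("x1", "x2", "x3"),
               linear_features = character(0), outcome = "y")
  expect_true(all(g$smooth_terms$edf <= 1.5))
  lin <- fit_linear(d, c("x1", "x2", "x3"), outcome = "y")
  cmp <- compare_models(lin, g)
  expect_lt(abs(cmp$delta_aic), 2)
  # a GAM restricted to pure linear terms equals the linear model exactly
  g0 <- fit_gam(d, smooth_features = character(0),
                linear_features = c("x1", "x2", "x3"), outcome = "y")
  expect_lt(abs(g0$aic - lin$aic), 2)
})

test_that("GAM recovers planted nonlinear shapes", {
  # inverted-U age effect peaking at 64 years
  d <- withr::with_seed(50, {
    age <- runif(1500, 56, 74)
    data.frame(age = age,
               y = 2 - 0.02 * (age - 64)^2 + rnorm(1500, 0, 0.5))
  })
  g <- fit_gam(d, smooth_features = "age", linear_features = character(0),
               outcome = "y")
  curve <- g$curves$age
  expect_lt(abs(curve$x[which.max(curve$fit)] - 64), 3)

  # monotone VRT effect stays monotone over the central 90% of VRT
  d2 <- withr::with_seed(51, {
    v <- rexp(1500, 1 / 2)
    data.frame(vrt_seconds = v, y = log1p(v) + rnorm(1500, 0, 0.4))
  })
  g2 <- fit_gam(d2, smooth_features = "vrt_seconds",
                linear_features = character(0), outcome = "y")
  cv <- g2$curves$vrt_seconds
  qs <- quantile(d2$vrt_seconds, c(0.05, 0.95))
  mid <- cv$fit[cv$x >= qs[1] & cv$x <= qs[2]]
  expect_true(all(diff(mid) > -1e-6))
})

test_that("basis size adapts to low-cardinality covariates or errors", {
  obs <- small_obs(seed = 13)
  g <- fit_gam(obs)   # caffeine has few unique counts; k shrinks silently
  expect_true(all(is.finite(g$smooth_terms$edf)))
  expect_error(fit_gam(obs, adapt_k = FALSE), class = "argument_error")
})

test_that("model comparison prefers the GAM under a nonlinear truth", {
  d <- withr::with_seed(60, {
    x <- runif(1500, 0, 6)
    data.frame(x1 = x, y = sin(x) + rnorm(1500, 0, 0.4))
  })
  g <- fit_gam(d, smooth_features = "x1", linear_features = character(0),
               outcome = "y")
  lin <- fit_linear(d, "x1", outcome = "y")
  cmp <- compare_models(lin, g)
  expect_lt(cmp$aic_gam, cmp$aic_linear)
  expect_identical(cmp$winner, "gam")
  expect_lt(cmp$anova_p, 0.001)

  # specificity: under a linear truth the approximate ANOVA rarely rejects
  ps <- vapply(1:10, function(s) {
    dl <- linear_truth_data(500, seed = 70 + s, noise_sd = 0.5)
    gl <- fit_gam(dl, smooth_features = c("x1", "x2"),
                  linear_features = "x3", outcome = "y")
    ll <- fit_linear(dl, c("x1", "x2", "x3"), outcome = "y")
    compare_models(ll, gl)$anova_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("the association cascade follows the RESET branch", {
  obs <- small_obs(seed = 30)
  res <- run_association(obs, seed = 2)
  expect_s3_class(res$screening, "importance_table")
  expect_s3_class(res$linear, "linear_fit")
  if (res$reset_p <= 0.05) {
    expect_s3_class(res$gam, "gam_fit")
    expect_s3_class(res$comparison, "model_comparison")
    expect_identical(res$comparison$delta_aic,
                     res$linear$aic - res$gam$aic)
  } else {
    expect_null(res$gam)
    expect_null(res$comparison)
  }
})
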