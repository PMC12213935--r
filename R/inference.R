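#' Random-forest importance screening
#'
#' Ranks candidate predictors of sleepiness by random-forest node-purity
#' importance (total impurity decrease summed over trees) and applies an
#' absolute cutoff: features with importance below the cutoff are dropped,
#' minus any manual exclusions, which are removed from the candidate set
#' outright (race is excluded by default to avoid imbalance artifacts).
#'
#' Node-purity totals are implementation- and sample-size-scaled, so the
#' default absolute cutoff of 50 is a convention, not a universal constant;
#' `cutoff_quantile` instead drops features below the given quantile of the
#' observed importances.
#'
#' @param data Observation table.
#' @param outcome Outcome column name (numeric sleepiness 1-4).
#' @param candidates Character vector of candidate feature columns.
#' @param cutoff Absolute node-purity cutoff.
#' @param cutoff_quantile If non-`NULL`, overrides `cutoff` with the given
#'   quantile of the importances.
#' @param manual_exclusions Features removed a priori.
#' @param num_trees Number of trees.
#' @param seed Integer seed.
#' @return An `importance_table` list: `importance` (named vector),
#'   `cutoff`, `retained`, `dropped`, `manually_excluded`.
#' @export
screen_features <- function(data, outcome = "sleepiness",
                            candidates = c("vrt_seconds", "cognition_scale",
                                           "mood", "age", "sex", "caffeine",
                                           "bzra_use", "education",
                                           "difficulty", "pass_fail",
                                           "alcohol", "race"),
                            cutoff = 50, cutoff_quantile = NULL,
                            manual_exclusions = "race",
                            num_trees = 500, seed = 1L) {
  miss <- setdiff(c(outcome, candidates), names(data))
  if (length(miss)) {
    abort_vrt(paste0("missing column(s): ", paste(miss, collapse = ", ")),
              "schema_error")
  }
  y <- as.numeric(data[[outcome]])
  if (stats::sd(y) == 0) {
    abort_vrt("outcome is constant; no impurity to reduce", "screening_error")
  }
  feats <- setdiff(candidates, manual_exclusions)
  x <- as.data.frame(data[, feats])
  x[] <- lapply(x, function(v) if (is.character(v)) factor(v) else v)
  # regression forest on the numeric 1-4 outcome; the few-unique-values
  # warning is expected for an ordinal response and muffled
  rf <- with_seed(seed, withCallingHandlers(
    randomForest::randomForest(x = x, y = y, ntree = num_trees,
                               importance = FALSE),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  cut_val <- if (!is.null(cutoff_quantile)) {
    stats::quantile(imp, cutoff_quantile, names = FALSE)
  } else {
    cutoff
  }
  structure(list(importance = imp,
                 cutoff = cut_val,
                 retained = names(imp)[imp >= cut_val],
                 dropped = names(imp)[imp < cut_val],
                 manually_excluded = intersect(manual_exclusions, candidates)),
            class = "importance_table")
}

# reference-coded model frame shared by the linear model and the GAM
code_covariates <- function(data) {
  d <- as.data.frame(data)
  if ("sex" %in% names(d)) d$sex <- stats::relevel(factor(d$sex), ref = "female")
  if ("mood" %in% names(d)) d$mood <- factor(d$mood, levels = sort(unique(d$mood)))
  if ("bzra_use" %in% names(d)) d$bzra_use <- factor(d$bzra_use, levels = c(FALSE, TRUE))
  if ("pass_fail" %in% names(d)) d$pass_fail <- factor(d$pass_fail, levels = c(FALSE, TRUE))
  if ("alcohol" %in% names(d)) d$alcohol <- factor(d$alcohol, levels = c(FALSE, TRUE))
  d
}

#' Ordinary least-squares fit of sleepiness on selected features
#'
#' Sleepiness (1-4) is modeled as numeric with Gaussian error. Categorical
#' covariates are reference-coded: female, mood level 1 and BZRA non-use are
#' the reference levels. Returns a term table suitable for forest-plot
#' rendering, with 95% normal-approximation CIs (estimate +/- 1.96 SE).
#'
#' @param data Observation table.
#' @param features Character vector of predictor columns.
#' @param outcome Outcome column name.
#' @return A `linear_fit` list: `terms` (tibble), `r_squared`, `aic`, `n`,
#'   `model` (the underlying `lm`).
#' @export
fit_linear <- function(data, features, outcome = "sleepiness") {
  d <- code_covariates(data[, c(outcome, features)])
  if (nrow(d) <= length(features) + 1) {
    abort_vrt("need n greater than the number of parameters", "argument_error")
  }
  const <- features[vapply(d[features], function(v) length(unique(v)) < 2, TRUE)]
  if (length(const)) {
    abort_vrt(paste0("constant feature(s): ", paste(const, collapse = ", ")),
              "argument_error")
  }
  fml <- stats::reformulate(features, response = outcome)
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit)))) {
    abort_vrt(paste0("rank-deficient fit; collinear term(s): ",
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")), "argument_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  z <- stats::qnorm(0.975)
  terms <- tibble::tibble(term = rownames(co),
                          estimate = co[, 1], se = co[, 2],
                          ci_low = co[, 1] - z * co[, 2],
                          ci_high = co[, 1] + z * co[, 2],
                          p_value = co[, 4])
  # a constant outcome has no variance to explain: report 0, not NaN
  r2 <- if (stats::var(d[[outcome]]) == 0) 0 else sm$r.squared
  structure(list(terms = terms, r_squared = r2,
                 aic = stats::AIC(fit), n = nrow(d), model = fit,
                 features = features, outcome = outcome, data = d),
            class = "linear_fit")
}

#' Forest plot of linear-model terms
#'
#' @param fit A [fit_linear()] result.
#' @return A ggplot object (point estimates with 95% CIs, intercept
#'   omitted).
#' @export
plot_forest <- function(fit) {
  tt <- fit$terms[fit$terms$term != "(Intercept)", ]
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "effect on sleepiness (per unit / vs reference)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' RESET misspecification test
#'
#' Ramsey's regression specification error test: an F-test of whether powers
#' of the fitted values (squares and cubes by default) improve the linear
#' model. A small p-value signals unmodeled nonlinearity, which in this
#' pipeline triggers the GAM stage.
#'
#' @param fit A [fit_linear()] result.
#' @param powers Integer powers of the fitted values to add.
#' @return The RESET p-value.
#' @export
reset_test <- function(fit, powers = 2:3) {
  stopifnot(inherits(fit, "linear_fit"))
  as.numeric(lmtest::resettest(fit$model, power = powers,
                               type = "fitted")$p.value)
}

#' Penalized-spline generalized additive model of sleepiness
#'
#' Fits a Gaussian GAM on the numeric 1-4 sleepiness outcome with
#' thin-plate penalized smooths for the continuous covariates (VRT, age,
#' education, caffeine intake, test difficulty by default) and parametric
#' terms for the rest (sex, BZRA use, mood, cognition scale). Smoothing
#' parameters are selected by REML, which shrinks unneeded smooths to
#' near-linearity far more reliably than GCV (GCV remains available via
#' `method`). The basis size per smooth is capped at
#' one less than the number of unique covariate values when
#' `adapt_k = TRUE` (needed for low-cardinality counts such as caffeine);
#' with `adapt_k = FALSE` an oversized basis errors with a suggestion to
#' lower `k`. AIC is computed on the same Gaussian likelihood scale as
#' [fit_linear()], so the two are directly comparable.
#'
#' @param data Observation table.
#' @param smooth_features Continuous covariates to smooth.
#' @param linear_features Covariates entering parametrically.
#' @param outcome Outcome column name.
#' @param k Basis dimension per smooth.
#' @param method Smoothness-selection criterion (`"REML"` or `"GCV.Cp"`).
#' @param adapt_k Shrink k to the covariate's support when needed.
#' @return A `gam_fit` list: `smooth_terms` (term, edf, p_value),
#'   `linear_terms`, `aic`, `deviance_explained`, `curves` (per-smooth grid
#'   tibbles with `x`, `fit`, `se`), `model`.
#' @export
fit_gam <- function(data,
                    smooth_features = c("vrt_seconds", "age", "education",
                                        "caffeine", "difficulty"),
                    linear_features = c("sex", "bzra_use", "mood",
                                        "cognition_scale"),
                    outcome = "sleepiness", k = 10, method = "REML",
                    adapt_k = TRUE) {
  d <- code_covariates(data[, c(outcome, smooth_features, linear_features)])
  ks <- vapply(smooth_features, function(f) {
    u <- length(unique(d[[f]]))
    if (k > u - 1) {
      if (!adapt_k) {
        abort_vrt(sprintf("basis size k = %d exceeds unique values of %s (%d); use a smaller k",
                          k, f, u), "argument_error")
      }
      max(3L, u - 1L)
    } else {
      as.integer(k)
    }
  }, integer(1))
  sm <- sprintf("s(%s, k = %d)", smooth_features, ks)
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(c(sm, linear_features), collapse = " + ")))
  fit <- mgcv::gam(fml, data = d, method = method)
  s <- summary(fit)
  smooth_terms <- tibble::tibble(
    term = rownames(s$s.table),
    edf = s$s.table[, "edf"],
    p_value = s$s.table[, "p-value"])
  pco <- s$p.table
  z <- stats::qnorm(0.975)
  linear_terms <- tibble::tibble(term = rownames(pco),
                                 estimate = pco[, 1], se = pco[, 2],
                                 ci_low = pco[, 1] - z * pco[, 2],
                                 ci_high = pco[, 1] + z * pco[, 2],
                                 p_value = pco[, 4])
  curves <- lapply(smooth_features, function(f) {
    grid <- d[rep(1, 200), c(smooth_features, linear_features), drop = FALSE]
    for (g in smooth_features) grid[[g]] <- stats::median(d[[g]])
    grid[[f]] <- seq(min(d[[f]]), max(d[[f]]), length.out = 200)
    pr <- mgcv::predict.gam(fit, newdata = grid, type = "terms", se.fit = TRUE)
    col <- grep(paste0("s\\(", f, "\\)"), colnames(pr$fit))
    tibble::tibble(x = grid[[f]], fit = pr$fit[, col], se = pr$se.fit[, col])
  })
  names(curves) <- smooth_features
  structure(list(smooth_terms = smooth_terms, linear_terms = linear_terms,
                 aic = stats::AIC(fit),
                 deviance_explained = s$dev.expl,
                 curves = curves, model = fit, n = nrow(d),
                 outcome = outcome),
            class = "gam_fit")
}

#' Plot fitted GAM smooths
#'
#' @param fit A [fit_gam()] result.
#' @return A ggplot object, one panel per smooth, with 95% bands.
#' @export
plot_smooths <- function(fit) {
  df <- dplyr::bind_rows(lapply(names(fit$curves), function(f) {
    cbind(term = f, fit$curves[[f]])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit - 1.96 * .data$se,
                                      ymax = .data$fit + 1.96 * .data$se),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect on sleepiness") +
    ggplot2::theme_minimal()
}

#' Compare the linear model and the GAM
#'
#' Reports the AIC difference (linear minus GAM; positive values favor the
#' GAM) and an approximate F-test of the nested comparison, computed by
#' refitting the linear model in the same penalized framework and comparing
#' residual sums of squares on effective degrees of freedom. The comparison
#' is approximate because the GAM's degrees of freedom are penalized
#' (non-integer); when the smooths have shrunk so far that the effective
#' degree-of-freedom difference is below 0.5 the two models are reported as
#' equivalent (p = 1) rather than feeding a degenerate F reference.
#'
#' @param lin A [fit_linear()] result.
#' @param gam A [fit_gam()] result.
#' @return A `model_comparison` list: `aic_linear`, `aic_gam`, `delta_aic`,
#'   `anova_p`, `winner`.
#' @export
compare_models <- function(lin, gam) {
  stopifnot(inherits(lin, "linear_fit"), inherits(gam, "gam_fit"))
  if (lin$n != gam$n) abort_vrt("models fitted on different row counts",
                                "comparison_error")
  g0 <- mgcv::gam(stats::formula(lin$model), data = lin$data,
                  method = gam$model$method)
  a <- stats::anova(g0, gam$model, test = "F")
  d_df <- a$Df[2]
  p <- if (is.na(d_df) || d_df < 0.5 || is.na(a[["Pr(>F)"]][2])) {
    1.0
  } else {
    a[["Pr(>F)"]][2]
  }
  delta <- lin$aic - gam$aic
  structure(list(aic_linear = lin$aic, aic_gam = gam$aic, delta_aic = delta,
                 anova_p = p,
                 winner = if (delta > 0) "gam" else "linear"),
            class = "model_comparison")
}

#' Association-modeling cascade
#'
#' Runs the full association pipeline in order: random-forest importance
#' screening of candidate predictors, the linear model on the retained set,
#' the RESET misspecification test, and — if RESET rejects at the chosen
#' alpha — the GAM plus AIC/ANOVA model comparison. The GAM smooths are the
#' retained continuous covariates; retained categorical/ordinal covariates
#' enter parametrically.
#'
#' @param data Observation table.
#' @param cutoff Node-purity cutoff for screening.
#' @param reset_alpha Significance level gating the GAM stage.
#' @param seed Integer seed (screening randomness).
#' @param ... Further arguments to [screen_features()].
#' @return A list: `screening`, `linear`, `reset_p`, `gam` (`NULL` when the
#'   RESET test does not reject), `comparison` (`NULL` likewise).
#' @export
run_association <- function(data, cutoff = 50, reset_alpha = 0.05,
                            seed = 1L, ...) {
  scr <- screen_features(data, cutoff = cutoff, seed = seed, ...)
  if (length(scr$retained) == 0) {
    abort_vrt("screening retained no features; lower the cutoff (node-purity totals scale with sample size)",
              "screening_error")
  }
  lin <- fit_linear(data, scr$retained)
  p_reset <- reset_test(lin)
  gam <- NULL; cmp <- NULL
  if (p_reset <= reset_alpha) {
    smooth_pool <- c("vrt_seconds", "age", "education", "caffeine", "difficulty")
    sm <- intersect(scr$retained, smooth_pool)
    linf <- setdiff(scr$retained, sm)
    gam <- fit_gam(data, smooth_features = sm, linear_features = linf)
    cmp <- compare_models(lin, gam)
  }
  list(screening = scr, linear = lin, reset_p = p_reset,
       gam = gam, comparison = cmp)
}
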