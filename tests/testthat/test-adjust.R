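test_that("intercept-only fit recovers the sample proportion", {
  y <- c(rep(1, 7), rep(0, 13))
  fit <- fit_logistic(matrix(numeric(0), nrow = 20, ncol = 0), y)
  expect_true(fit$converged)
  expect_equal(plogis(fit$coefficients[["(Intercept)"]]), 7 / 20,
               tolerance = 1e-10)
})

test_that("a 2x2 design reproduces the contingency-table odds ratio", {
  tab <- table2x2_data(a = 18, b = 32, c = 41, d = 29)
  fit <- fit_logistic(tab$design, tab$response)
  expect_true(fit$converged)
  expect_equal(exp(fit$coefficients[["exposure"]]), tab$or, tolerance = 1e-8)
  or <- odds_ratio(fit, "exposure")
  expect_equal(or$or, tab$or, tolerance = 1e-8)
  # Wald CI from hand-computed cell-count standard error
  se <- sqrt(1 / 18 + 1 / 32 + 1 / 41 + 1 / 29)
  expect_equal(or$ci_low, exp(log(tab$or) - qnorm(0.975) * se),
               tolerance = 1e-6)
  expect_equal(or$ci_high, exp(log(tab$or) + qnorm(0.975) * se),
               tolerance = 1e-6)
})

test_that("odds_ratio transforms coefficients and flags unknown terms", {
  fit <- manual_fit(c("(Intercept)" = 0, ambulatory = log(2)),
                    ses = c(0.5, 0.1))
  or <- odds_ratio(fit, "ambulatory")
  expect_equal(or$or, 2)
  expect_equal(or$ci_low, exp(log(2) - qnorm(0.975) * 0.1), tolerance = 1e-10)
  expect_equal(or$ci_high, exp(log(2) + qnorm(0.975) * 0.1), tolerance = 1e-10)
  expect_equal(or$p_value, 2 * pnorm(-log(2) / 0.1), tolerance = 1e-10)
  null <- odds_ratio(manual_fit(c("(Intercept)" = 1, ambulatory = 0),
                                ses = c(1, 0.3)), "ambulatory")
  expect_equal(null$or, 1)
  expect_true(null$ci_low < 1 && null$ci_high > 1)
  expect_error(odds_ratio(fit, "nope"), "unknown term")
})

test_that("adjusted probabilities follow the inverse-logit identities", {
  fit0 <- manual_fit(c("(Intercept)" = 0, ambulatory = 0, age = 0),
                     ses = c(1, 1, 1))
  expect_equal(adjusted_probability(fit0, c(age = 50), "non_ambulatory"), 0.5)
  expect_equal(adjusted_probability(fit0, c(age = 50), "ambulatory"), 0.5)
  # intercept-only fit returns its probability regardless of group
  fit1 <- manual_fit(c("(Intercept)" = qlogis(0.3)), ses = 0.2)
  expect_equal(adjusted_probability(fit1, numeric(0), "ambulatory"), 0.3)
  # monotone in a positively-weighted covariate
  fit2 <- manual_fit(c("(Intercept)" = -1, ambulatory = 0.5, age = 0.02),
                     ses = c(1, 1, 1))
  ps <- vapply(c(20, 40, 60, 80),
               function(a) adjusted_probability(fit2, c(age = a), "ambulatory"),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_error(adjusted_probability(fit2, c(weight = 70), "ambulatory"),
               "covariate_means")
})

test_that("degenerate designs are flagged, not silently fitted", {
  n <- 50
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.5)
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), y), "rank deficient.*b")
  expect_error(fit_logistic(cbind(a = x), rep(1, n)), "constant")
  # perfect separation (glm.fit also warns about 0/1 fitted probabilities)
  xs <- c(rep(0, 20), rep(1, 20))
  warns <- capture_warnings(fit <- fit_logistic(cbind(x = xs), xs))
  expect_true(any(grepl("separation", warns)))
  expect_false(fit$converged)
})

test_that("the score vanishes at the reported optimum across random designs", {
  set.seed(81)
  for (i in 1:5) {
    n <- 300
    X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 1] - 0.5 * X[, 2]))
    fit <- fit_logistic(X, y)
    expect_true(fit$converged)
    expect_lt(fit$max_abs_score, 1e-6)
  }
})

test_that("adjustment stage recovers generating probabilities end-to-end", {
  om <- ambucost:::default_outcome_model()
  om$uti$rate_non_ambulatory <- c(y1 = 0.733, y5 = 0.624)
  p <- synth_params(n_patients = 20000, seed = 7, rate_reference = "pooled",
                    outcome_model = om)
  adj <- adjust_cohort(generate_cohort(p), waves = "y1", means = "pooled")
  uti <- adj$table[adj$table$outcome == "uti", ]
  expect_true(all(adj$table$converged))
  expect_lt(abs(uti$p_non_ambulatory - 0.733), 0.03)
  expect_lt(abs(uti$p_ambulatory - 0.556), 0.03)
  # and the generating odds ratio sits inside the fitted CI
  expect_gt(0.454, uti$ci_low)
  expect_lt(0.454, uti$ci_high)
})

test_that("adjustment table maps onto Markov model inputs", {
  co <- generate_cohort(synth_params(n_patients = 8000, seed = 13))
  adj <- adjust_cohort(co)
  inp <- as_model_inputs(adj$table)
  r <- adj$table[adj$table$outcome == "uti" & adj$table$wave == "y1", ]
  expect_equal(unname(inp$groups$non_ambulatory$p_uti[["y1"]]),
               r$p_non_ambulatory)
  expect_equal(unname(inp$groups$ambulatory$p_uti[["y1"]]), r$p_ambulatory)
  expect_s3_class(inp, "model_inputs")
})
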