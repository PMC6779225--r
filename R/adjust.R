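# Covariate-adjusted complication probabilities.
#
# Each complication (UTI, pressure sore, all-cause hospitalization) at each
# follow-up wave is regressed on an ambulatory indicator plus age, sex,
# marital status, employment, ASIA grade (reference A; "unknown" dropped)
# and injury level (reference T1-T6). The ambulation odds ratio with a Wald
# 95% CI summarizes the independent association; evaluating the fitted model
# at covariate means with the group indicator at 0/1 yields the adjusted
# annual probabilities that feed the Markov model.

#' Fit a logistic regression by maximum likelihood
#'
#' A thin wrapper around iteratively reweighted least squares
#' (`stats::glm.fit`) that returns the coefficient vector, its covariance
#' matrix, and an explicit convergence flag based on the score at the
#' optimum. Rank-deficient designs and apparent separation are flagged
#' rather than silently returned.
#'
#' @param design Numeric matrix of predictors, one column per term,
#'   without an intercept column (one is added).
#' @param response Binary (0/1 or logical) outcome vector.
#' @param outcome,wave Optional labels stored on the fit.
#' @return An object of class `logistic_fit`: coefficients, `vcov`,
#'   `n_used`, `converged`, labels.
#' @export
fit_logistic <- function(design, response, outcome = "outcome", wave = "y1") {
  design <- as.matrix(design)
  if (is.null(colnames(design)) && ncol(design) > 0) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  response <- as.numeric(response)
  if (anyNA(design) || anyNA(response)) abort("missing values in design or response")
  if (!all(response %in% c(0, 1))) abort("response must be binary")
  if (length(unique(response)) < 2) abort("response is constant; cannot fit")
  X <- cbind("(Intercept)" = 1, design)
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    abort("design is rank deficient; offending column(s): %s",
          paste(bad, collapse = ", "))
  }
  fit <- stats::glm.fit(X, response, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-12,
                                                     maxit = 100))
  beta <- fit$coefficients
  p <- fit$fitted.values
  w <- p * (1 - p)
  vcov <- chol2inv(chol(crossprod(X * sqrt(w))))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  score <- drop(crossprod(X, response - p))
  converged <- isTRUE(fit$converged) && max(abs(score)) < 1e-6
  if (any(abs(beta) > 15) || any(sqrt(diag(vcov)) > 100)) {
    warning("possible separation: extreme coefficient or standard error",
            call. = FALSE)
    converged <- FALSE
  }
  structure(list(coefficients = beta, vcov = vcov, n_used = nrow(X),
                 converged = converged, outcome = outcome, wave = wave,
                 max_abs_score = max(abs(score))),
            class = "logistic_fit")
}

#' Odds ratio with Wald 95% confidence interval for one model term
#'
#' @param fit A [fit_logistic()] object.
#' @param term Coefficient name, e.g. `"ambulatory"`.
#' @return One-row data frame: `term`, `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
odds_ratio <- function(fit, term = "ambulatory") {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!term %in% names(fit$coefficients)) {
    abort("unknown term '%s'; available: %s", term,
          paste(names(fit$coefficients), collapse = ", "))
  }
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- stats::qnorm(0.975)
  data.frame(term = term, or = exp(b), ci_low = exp(b - z * se),
             ci_high = exp(b + z * se),
             p_value = 2 * stats::pnorm(-abs(b / se)),
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted probability for one ambulation group
#'
#' Inverse-logit of the fitted linear predictor evaluated at the supplied
#' covariate means with the ambulatory indicator set to 0 or 1.
#'
#' @param fit A [fit_logistic()] object whose design included a term named
#'   `group_term`.
#' @param covariate_means Named numeric vector covering every coefficient
#'   except the intercept and the group indicator.
#' @param group `"ambulatory"` or `"non_ambulatory"`.
#' @param group_term Name of the group indicator column.
#' @return Probability in \[0, 1\].
#' @export
adjusted_probability <- function(fit, covariate_means,
                                 group = c("non_ambulatory", "ambulatory"),
                                 group_term = "ambulatory") {
  stopifnot(inherits(fit, "logistic_fit"))
  group <- match.arg(group)
  b <- fit$coefficients
  need <- setdiff(names(b), c("(Intercept)", group_term))
  if (length(need) && (is.null(names(covariate_means)) ||
                       !setequal(names(covariate_means), need))) {
    abort("covariate_means must be named and cover exactly: %s",
          paste(need, collapse = ", "))
  }
  g <- if (group_term %in% names(b)) b[[group_term]] * (group == "ambulatory") else 0
  lp <- b[["(Intercept)"]] + g +
    if (length(need)) sum(b[need] * covariate_means[need]) else 0
  stats::plogis(lp)
}

# Design matrix for the adjustment stage of one wave. Drops partial-ability
# (excluded) patients, unknown ASIA grade, patients missing the wave, and
# incomplete covariate rows.
build_design <- function(cohort, wave = c("y1", "y5")) {
  wave <- match.arg(wave)
  cls <- classify_ambulation(cohort$walk_150ft, cohort$walk_one_block,
                             cohort$climb_one_flight)
  keep <- cls %in% c("ambulatory", "non_ambulatory") &
    cohort$asia_grade %in% c("A", "B", "C", "D")
  if (wave == "y5") keep <- keep & cohort$followup_y5
  d <- cohort[keep, ]
  cls <- cls[keep]
  X <- cbind(ambulatory = as.numeric(cls == "ambulatory"),
             age = d$age, male = as.numeric(d$sex == "male"),
             married = as.numeric(d$married),
             employed = as.numeric(d$employed),
             asia_B = as.numeric(d$asia_grade == "B"),
             asia_C = as.numeric(d$asia_grade == "C"),
             asia_D = as.numeric(d$asia_grade == "D"),
             t7t12 = as.numeric(d$injury_level == "T7-T12"))
  y <- d[, paste0(c("uti", "psore", "hosp_any"), "_", wave)]
  names(y) <- c("uti", "psore", "hosp_any")
  cc <- stats::complete.cases(X) & stats::complete.cases(y)
  list(design = X[cc, , drop = FALSE], outcomes = y[cc, , drop = FALSE],
       n = sum(cc))
}

#' Run the full adjustment stage on a cohort
#'
#' Classifies ambulation, fits one logistic model per complication per wave,
#' and reports the ambulation odds ratio (Wald 95% CI, p-value) together
#' with covariate-adjusted annual probabilities for both groups.
#'
#' @param cohort A cohort data frame ([generate_cohort()] / [read_cohort()]).
#' @param waves Follow-up waves to fit.
#' @param means Covariate means at which adjusted probabilities are
#'   evaluated: `"pooled"` (both groups at the shared analysis-sample means;
#'   the default) or `"group"` (each group at its own means).
#' @return List with `fits` (named `logistic_fit` objects) and `table`, a
#'   data frame with one row per outcome and wave: n, OR, CI, p-value, and
#'   adjusted probabilities per group.
#' @export
adjust_cohort <- function(cohort, waves = c("y1", "y5"),
                          means = c("pooled", "group")) {
  means <- match.arg(means)
  fits <- list()
  rows <- list()
  for (w in waves) {
    bd <- build_design(cohort, w)
    covcols <- setdiff(colnames(bd$design), "ambulatory")
    mns <- list(
      pooled = colMeans(bd$design[, covcols, drop = FALSE]),
      non_ambulatory = colMeans(bd$design[bd$design[, "ambulatory"] == 0,
                                          covcols, drop = FALSE]),
      ambulatory = colMeans(bd$design[bd$design[, "ambulatory"] == 1,
                                      covcols, drop = FALSE]))
    for (o in names(bd$outcomes)) {
      fit <- fit_logistic(bd$design, bd$outcomes[[o]], outcome = o, wave = w)
      fits[[paste(o, w, sep = "_")]] <- fit
      or <- odds_ratio(fit, "ambulatory")
      m_na <- if (means == "pooled") mns$pooled else mns$non_ambulatory
      m_am <- if (means == "pooled") mns$pooled else mns$ambulatory
      rows[[length(rows) + 1]] <- data.frame(
        outcome = o, wave = w, n = bd$n, converged = fit$converged,
        or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
        p_value = or$p_value,
        p_non_ambulatory = adjusted_probability(fit, m_na, "non_ambulatory"),
        p_ambulatory = adjusted_probability(fit, m_am, "ambulatory"),
        stringsAsFactors = FALSE)
    }
  }
  list(fits = fits, table = do.call(rbind, rows))
}

#' Convert an adjustment table into Markov model inputs
#'
#' Overwrites the annual event probabilities of a base [model_inputs()]
#' object with the adjusted probabilities estimated from a cohort.
#'
#' @param adjust_table The `table` element of [adjust_cohort()] containing
#'   both waves.
#' @param base A [model_inputs()] object providing every non-estimated field.
#' @return A `model_inputs` object.
#' @export
as_model_inputs <- function(adjust_table, base = model_inputs()) {
  key <- c(uti = "p_uti", psore = "p_psore", hosp_any = "p_hosp")
  for (i in seq_len(nrow(adjust_table))) {
    r <- adjust_table[i, ]
    for (g in c("non_ambulatory", "ambulatory")) {
      base <- set_in(base, paste("groups", g, key[[r$outcome]], r$wave, sep = "."),
                     r[[paste0("p_", g)]])
    }
  }
  validate_inputs(base)
}
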