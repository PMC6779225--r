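# Construct a logistic_fit by hand (for testing downstream operations
# independently of the fitting routine).
manual_fit <- function(coefs, ses) {
  structure(list(coefficients = coefs,
                 vcov = diag(ses^2, nrow = length(coefs),
                             ncol = length(coefs)) |>
                   `dimnames<-`(list(names(coefs), names(coefs))),
                 n_used = NA_integer_, converged = TRUE,
                 outcome = "test", wave = "y1"),
            class = "logistic_fit")
}

# Expand a 2x2 contingency table (exposure x outcome) into unit records.
table2x2_data <- function(a, b, c, d) {
  # a: exposed w/ event, b: exposed w/o, c: unexposed w/ event, d: unexposed w/o
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(design = cbind(exposure = x), response = y, or = (a * d) / (b * c))
}

# Small model inputs for fast engine tests.
toy_inputs <- function(horizon_months = 12, p_death_annual = 0.3, ...) {
  model_inputs(
    horizon_months = horizon_months,
    groups = list(
      non_ambulatory = group_inputs(
        p_uti = c(y1 = 0.4, y5 = 0.4), p_psore = c(y1 = 0, y5 = 0),
        p_hosp = c(y1 = 0.24, y5 = 0.24),
        cond_hosp_uti = c(y1 = 0, y5 = 0), cond_hosp_psore = c(y1 = 0, y5 = 0)),
      ambulatory = group_inputs(
        p_uti = c(y1 = 0.2, y5 = 0.2), p_psore = c(y1 = 0, y5 = 0),
        p_hosp = c(y1 = 0.12, y5 = 0.12),
        cond_hosp_uti = c(y1 = 0, y5 = 0), cond_hosp_psore = c(y1 = 0, y5 = 0))),
    p_death_annual = p_death_annual, cohort_size = 100, ...)
}
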