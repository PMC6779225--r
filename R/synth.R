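# Synthetic registry-style cohort generator.
#
# Emulates the structure of a spinal-cord-injury registry extract: baseline
# covariates, three self-reported mobility items, and annual complication
# outcomes (UTI, pressure sore, all-cause hospitalization with conditional
# hospitalization sub-flags) at one- and five-year follow-up. Covariates are
# drawn independently within latent ambulation class; outcomes follow a
# logistic model on ambulation plus covariates.

#' Default covariate distributions by latent ambulation class
#'
#' Group-wise marginals matching the one-year descriptive characteristics
#' of the registry population: age (truncated normal), sex, marital and
#' employment status (Bernoulli), ASIA grade (categorical, A-D plus
#' unknown) and thoracic injury level. Modify the returned list to change
#' the emulated population.
#'
#' @return Nested list with elements `non_ambulatory`, `ambulatory`,
#'   `partial`.
#' @export
default_covariate_settings <- function() {
  na <- list(age_mean = 35.6, age_sd = 14.4, p_male = 0.800,
             p_married = 0.318, p_employed = 0.124,
             asia = c(A = 0.766, B = 0.117, C = 0.099, D = 0.017, unknown = 0.001),
             p_t1t6 = 0.481)
  am <- list(age_mean = 39.1, age_sd = 17.5, p_male = 0.754,
             p_married = 0.389, p_employed = 0.317,
             asia = c(A = 0.064, B = 0.026, C = 0.221, D = 0.686, unknown = 0.003),
             p_t1t6 = 0.323)
  # partial-ability patients never enter the fitted comparison; give them a
  # midpoint covariate profile
  pt <- Map(function(a, b) (unlist(a) + unlist(b)) / 2,
            na[names(na) != "asia"], am[names(am) != "asia"])
  pt$asia <- (na$asia + am$asia) / 2
  list(non_ambulatory = na, ambulatory = am, partial = pt)
}

# Per-outcome covariate effects on the log-odds scale. The ASIA-grade
# gradients are the dominant confounders: the ambulatory group is mostly
# grade D, the non-ambulatory group mostly grade A, so a strongly negative
# grade-D coefficient is what separates the large marginal rate gap from the
# smaller covariate-adjusted odds ratio.

#' Default outcome-generating logistic model
#'
#' Per outcome (UTI, pressure sore, all-cause hospitalization): covariate
#' log-odds coefficients, target non-ambulatory rates by wave, and
#' covariate-adjusted ambulation odds ratios by wave (0.454/0.256,
#' 0.235/0.264 and 0.585/0.567 at years 1/5). Intercepts are back-solved at
#' generation time from the target rates.
#'
#' @return Nested list with elements `uti`, `psore`, `hosp_any`.
#' @export
default_outcome_model <- function() {
  list(
    uti = list(
      coefs = c(age = -0.005, male = -0.10, married = -0.05, employed = -0.10,
                asia_B = -0.10, asia_C = -0.70, asia_D = -1.50, t7t12 = -0.10),
      rate_non_ambulatory = c(y1 = 0.757, y5 = 0.624),
      or_ambulatory = c(y1 = 0.454, y5 = 0.256)),
    psore = list(
      coefs = c(age = 0.005, male = 0.10, married = -0.10, employed = -0.20,
                asia_B = -0.30, asia_C = -1.20, asia_D = -2.50, t7t12 = -0.10),
      rate_non_ambulatory = c(y1 = 0.396, y5 = 0.377),
      or_ambulatory = c(y1 = 0.235, y5 = 0.264)),
    hosp_any = list(
      coefs = c(age = 0.010, male = 0.00, married = -0.10, employed = -0.20,
                asia_B = -0.10, asia_C = -0.30, asia_D = -0.60, t7t12 = -0.05),
      rate_non_ambulatory = c(y1 = 0.368, y5 = 0.341),
      or_ambulatory = c(y1 = 0.585, y5 = 0.567))
  )
}

#' Parameters for the synthetic cohort generator
#'
#' Defaults emulate the observed registry population: 18% ambulatory among
#' classifiable patients, group-wise covariate distributions matching the
#' descriptive table, outcome rates anchored to the non-ambulatory group
#' with covariate-adjusted ambulation odds ratios of 0.454/0.256 (UTI,
#' years 1/5), 0.235/0.264 (pressure sore) and 0.585/0.567 (hospitalization).
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; all draws derive from it.
#' @param p_ambulatory Probability of the ambulatory class among classifiable
#'   (non-partial) patients.
#' @param p_partial Fraction of patients with partial mobility ability, who
#'   are excluded by the classification rule.
#' @param p_followup_y5 Probability that a patient contributes the year-5
#'   follow-up wave.
#' @param covariates Per-class covariate distribution settings; see
#'   `default_covariate_settings()` for the structure.
#' @param outcome_model Per-outcome logistic settings: covariate
#'   coefficients, target non-ambulatory rates by wave, and ambulation odds
#'   ratios by wave; see `default_outcome_model()`.
#' @param rate_reference Where the target non-ambulatory rate is anchored:
#'   `"group"` calibrates the intercept at the non-ambulatory covariate
#'   means (so marginal group rates match the targets); `"pooled"`
#'   calibrates at pooled classifiable-population means (so the targets are
#'   recovered as adjusted-at-pooled-means probabilities).
#' @param cond_hosp Conditional hospitalization probabilities given UTI and
#'   given pressure sore, per group.
#' @param stays_mean,days_mean Group means for inpatient stays and days
#'   hospitalized among hospitalized patients.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_patients = 2000,
                         seed = 1,
                         p_ambulatory = 0.18,
                         p_partial = 0.15,
                         p_followup_y5 = 0.76,
                         covariates = default_covariate_settings(),
                         outcome_model = default_outcome_model(),
                         rate_reference = c("group", "pooled"),
                         cond_hosp = list(
                           uti = c(non_ambulatory = 0.168, ambulatory = 0.106),
                           psore = c(non_ambulatory = 0.191, ambulatory = 0.0)),
                         stays_mean = c(non_ambulatory = 1.7, ambulatory = 1.4),
                         days_mean = c(non_ambulatory = 16.7, ambulatory = 12.3)) {
  rate_reference <- match.arg(rate_reference)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    abort("'n_patients' must be a positive integer")
  }
  check_prob(p_ambulatory, "p_ambulatory")
  check_prob(p_partial, "p_partial")
  check_prob(p_followup_y5, "p_followup_y5")
  for (ev in names(cond_hosp)) check_prob(cond_hosp[[ev]], paste0("cond_hosp.", ev))
  for (o in names(outcome_model)) {
    check_prob(outcome_model[[o]]$rate_non_ambulatory,
               paste0(o, ".rate_non_ambulatory"))
    check_nonneg(outcome_model[[o]]$or_ambulatory, paste0(o, ".or_ambulatory"))
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 p_ambulatory = p_ambulatory, p_partial = p_partial,
                 p_followup_y5 = p_followup_y5, covariates = covariates,
                 outcome_model = outcome_model, rate_reference = rate_reference,
                 cond_hosp = cond_hosp, stays_mean = stays_mean,
                 days_mean = days_mean),
            class = "synth_params")
}

# Expected covariate mean vector (design scale) for one latent class.
class_mean_vector <- function(cv) {
  c(age = cv$age_mean, male = cv$p_male, married = cv$p_married,
    employed = cv$p_employed,
    asia_B = unname(cv$asia[["B"]]), asia_C = unname(cv$asia[["C"]]),
    asia_D = unname(cv$asia[["D"]]), t7t12 = 1 - cv$p_t1t6)
}

rtruncnorm <- function(n, mean, sd, lo = 18, hi = 90) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic patient cohort
#'
#' Draws latent ambulation class, covariates, mobility items consistent with
#' the class, and annual complication outcomes for the year-1 and (where
#' followed) year-5 waves. Outcomes are Bernoulli with logistic-model
#' probabilities; conditional hospitalization sub-flags are drawn only for
#' patients with the parent event, and all-cause hospitalization is forced
#' when a sub-flag fires, with the residual other-cause probability chosen so
#' the marginal hospitalization rate matches the logistic target.
#'
#' @param params A [synth_params()] object.
#' @return A data frame with one row per patient and attribute `params`.
#'   Outcome columns are suffixed `_y1` / `_y5`; year-5 columns are `NA` for
#'   patients without that wave.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  n <- params$n_patients

  cls <- ifelse(stats::runif(n) < params$p_partial, "partial",
                ifelse(stats::runif(n) < params$p_ambulatory,
                       "ambulatory", "non_ambulatory"))

  cv <- params$covariates
  age <- male <- married <- employed <- t1t6 <- numeric(n)
  asia <- character(n)
  for (g in c("non_ambulatory", "ambulatory", "partial")) {
    idx <- which(cls == g)
    if (!length(idx)) next
    s <- cv[[g]]
    age[idx] <- rtruncnorm(length(idx), s$age_mean, s$age_sd)
    male[idx] <- stats::rbinom(length(idx), 1, s$p_male)
    married[idx] <- stats::rbinom(length(idx), 1, s$p_married)
    employed[idx] <- stats::rbinom(length(idx), 1, s$p_employed)
    asia[idx] <- sample(names(s$asia), length(idx), replace = TRUE,
                        prob = s$asia / sum(s$asia))
    t1t6[idx] <- stats::rbinom(length(idx), 1, s$p_t1t6)
  }

  # mobility items consistent with the latent class; partial-ability patients
  # get one of the six mixed patterns
  mixed <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE), c = c(TRUE, FALSE))
  mixed <- mixed[rowSums(mixed) %in% 1:2, ]
  walk1 <- cls == "ambulatory"; walk2 <- walk1; climb <- walk1
  pidx <- which(cls == "partial")
  if (length(pidx)) {
    pick <- sample(nrow(mixed), length(pidx), replace = TRUE)
    walk1[pidx] <- mixed$a[pick]
    walk2[pidx] <- mixed$b[pick]
    climb[pidx] <- mixed$c[pick]
  }

  X <- cbind(age = age, male = male, married = married, employed = employed,
             asia_B = as.numeric(asia == "B"), asia_C = as.numeric(asia == "C"),
             asia_D = as.numeric(asia == "D"), t7t12 = 1 - t1t6)
  amb <- as.numeric(cls == "ambulatory")

  ref_means <- if (params$rate_reference == "group") {
    class_mean_vector(cv$non_ambulatory)
  } else {
    (1 - params$p_ambulatory) * class_mean_vector(cv$non_ambulatory) +
      params$p_ambulatory * class_mean_vector(cv$ambulatory)
  }

  cond_grp <- ifelse(cls == "ambulatory", "ambulatory", "non_ambulatory")
  followup_y5 <- stats::runif(n) < params$p_followup_y5

  out <- data.frame(id = sprintf("P%05d", seq_len(n)), age = age,
                    sex = ifelse(male == 1, "male", "female"),
                    married = married == 1, employed = employed == 1,
                    asia_grade = asia,
                    injury_level = ifelse(t1t6 == 1, "T1-T6", "T7-T12"),
                    walk_150ft = walk1, walk_one_block = walk2,
                    climb_one_flight = climb, followup_y5 = followup_y5,
                    stringsAsFactors = FALSE)

  for (w in c("y1", "y5")) {
    p_ev <- lapply(params$outcome_model, function(m) {
      alpha <- stats::qlogis(m$rate_non_ambulatory[[w]]) -
        sum(m$coefs[colnames(X)] * ref_means[colnames(X)])
      stats::plogis(alpha + log(m$or_ambulatory[[w]]) * amb +
                      drop(X %*% m$coefs[colnames(X)]))
    })
    uti <- stats::rbinom(n, 1, p_ev$uti) == 1
    psore <- stats::rbinom(n, 1, p_ev$psore) == 1
    c_u <- params$cond_hosp$uti[cond_grp]
    c_p <- params$cond_hosp$psore[cond_grp]
    uti_hosp <- uti & (stats::runif(n) < c_u)
    psore_hosp <- psore & (stats::runif(n) < c_p)
    # residual other-cause probability so marginal hospitalization matches
    p_sub <- 1 - (1 - p_ev$uti * c_u) * (1 - p_ev$psore * c_p)
    p_other <- pmin(1, pmax(0, (p_ev$hosp_any - p_sub) / (1 - p_sub)))
    hosp <- uti_hosp | psore_hosp | (stats::runif(n) < p_other)

    stays <- integer(n)
    days <- integer(n)
    hidx <- which(hosp)
    if (length(hidx)) {
      sm <- params$stays_mean[cond_grp[hidx]]
      dm <- params$days_mean[cond_grp[hidx]]
      stays[hidx] <- 1L + stats::rpois(length(hidx), sm - 1)
      days[hidx] <- 1L + stats::rnbinom(length(hidx), mu = dm - 1, size = 0.3)
    }

    wave <- data.frame(uti = uti, uti_hosp = uti_hosp, psore = psore,
                       psore_hosp = psore_hosp, hosp_any = hosp,
                       n_stays = stays, days_hosp = days)
    if (w == "y5") wave[!followup_y5, ] <- NA
    names(wave) <- paste0(names(wave), "_", w)
    out <- cbind(out, wave)
  }
  attr(out, "params") <- params
  out
}

cohort_columns <- function() {
  c("id", "age", "sex", "married", "employed", "asia_grade", "injury_level",
    "walk_150ft", "walk_one_block", "climb_one_flight", "followup_y5",
    paste0(rep(c("uti", "uti_hosp", "psore", "psore_hosp", "hosp_any",
                 "n_stays", "days_hosp"), 2),
           rep(c("_y1", "_y5"), each = 7)))
}

#' Write / read a cohort as CSV
#'
#' Fixed column order; logical fields encoded 0/1; a missing follow-up wave
#' is encoded by empty fields.
#'
#' @param cohort A cohort data frame from [generate_cohort()].
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame with logical columns
#'   restored.
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort[, cohort_columns()]
  for (j in names(df)) if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  logi <- c("married", "employed", "walk_150ft", "walk_one_block",
            "climb_one_flight", "followup_y5",
            grep("^(uti|psore|hosp_any)", cohort_columns(), value = TRUE))
  for (j in intersect(logi, names(df))) df[[j]] <- df[[j]] == 1
  df
}

#' Check outcome-set logical invariants for every record
#'
#' Verifies, for each available wave: a hospitalization sub-flag implies its
#' parent event and implies all-cause hospitalization, and a patient without
#' all-cause hospitalization has zero stays and zero days.
#'
#' @param cohort A cohort data frame.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_outcomes <- function(cohort) {
  for (w in c("y1", "y5")) {
    g <- function(col) cohort[[paste0(col, "_", w)]]
    ok <- stats::complete.cases(g("uti"), g("hosp_any"))
    imp <- function(a, b) all(!a[ok] | b[ok])
    if (!imp(g("uti_hosp"), g("uti")))
      abort("wave %s: uti_hosp without uti", w)
    if (!imp(g("psore_hosp"), g("psore")))
      abort("wave %s: psore_hosp without psore", w)
    if (!imp(g("uti_hosp") | g("psore_hosp"), g("hosp_any")))
      abort("wave %s: hospitalization sub-flag without hosp_any", w)
    if (!all(g("n_stays")[ok][g("hosp_any")[ok]] >= 1))
      abort("wave %s: hospitalized record with zero stays", w)
    no <- ok & !g("hosp_any")
    if (!all(g("n_stays")[no] == 0 & g("days_hosp")[no] == 0))
      abort("wave %s: stays/days recorded without hospitalization", w)
  }
  invisible(TRUE)
}
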