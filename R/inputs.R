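# Base-case model inputs and config-file handling.

#' Annual inputs for one ambulation group
#'
#' @param p_uti,p_psore,p_hosp Named vectors `c(y1 = , y5 = )` of annual
#'   probabilities of UTI, pressure sore and all-cause hospitalization at
#'   projection years 1 and 5 (years 2-4 are linearly interpolated).
#' @param cond_hosp_uti,cond_hosp_psore Conditional probabilities, at years
#'   1 and 5, that an event is accompanied by hospitalization for that cause.
#' @return A named list of class `group_inputs`.
#' @export
group_inputs <- function(p_uti, p_psore, p_hosp, cond_hosp_uti,
                         cond_hosp_psore) {
  g <- list(p_uti = p_uti, p_psore = p_psore, p_hosp = p_hosp,
            cond_hosp_uti = cond_hosp_uti, cond_hosp_psore = cond_hosp_psore)
  for (nm in names(g)) {
    if (!setequal(names(g[[nm]]), c("y1", "y5"))) {
      abort("'%s' must be a named vector with elements y1 and y5", nm)
    }
    check_prob(g[[nm]], nm)
  }
  structure(g, class = "group_inputs")
}

#' Base-case inputs for the Markov cohort model
#'
#' Defaults are the base-case parameter set: covariate-adjusted annual
#' complication probabilities per group at years 1 and 5, a flat 1.5% annual
#' death probability, 1.6 inpatient stays per hospitalized person-year, unit
#' costs in 2016 USD ($229 outpatient UTI, $1,803 outpatient pressure sore,
#' $17,985 per inpatient stay), a 3% annual discount rate, a 60-month
#' horizon and a cohort of 10,000. Year-5 conditional hospitalization
#' fractions are back-solved calibration defaults (see the methods
#' vignette).
#'
#' @param groups List with elements `non_ambulatory` and `ambulatory`, each
#'   a [group_inputs()] object.
#' @param p_death_annual Annual death probability (shared by both groups).
#' @param stays_per_hosp_year Inpatient stays per hospitalized person-year.
#' @param cost_uti_outpatient,cost_psore_outpatient,cost_inpatient_stay Unit
#'   costs, 2016 USD.
#' @param discount_rate_annual Annual discount rate.
#' @param horizon_months Model horizon; a positive multiple of 12.
#' @param cohort_size Closed-cohort size entering the model.
#' @param death_conversion Annual-to-monthly conversion for the mortality
#'   transition: `"compound"` (`1-(1-p)^(1/12)`, default) or `"simple"`
#'   (`p/12`).
#' @param outpatient_cost_scope Whether outpatient UTI / pressure-sore costs
#'   apply to `"all"` events (default) or only to `"nonhospitalized"` events.
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(
    groups = list(
      non_ambulatory = group_inputs(
        p_uti = c(y1 = 0.733, y5 = 0.624),
        p_psore = c(y1 = 0.331, y5 = 0.377),
        p_hosp = c(y1 = 0.347, y5 = 0.341),
        cond_hosp_uti = c(y1 = 0.168, y5 = 0.150),
        cond_hosp_psore = c(y1 = 0.191, y5 = 0.205)),
      ambulatory = group_inputs(
        p_uti = c(y1 = 0.556, y5 = 0.298),
        p_psore = c(y1 = 0.104, y5 = 0.138),
        p_hosp = c(y1 = 0.238, y5 = 0.227),
        cond_hosp_uti = c(y1 = 0.106, y5 = 0.030),
        cond_hosp_psore = c(y1 = 0, y5 = 0))),
    p_death_annual = 0.015,
    stays_per_hosp_year = 1.6,
    cost_uti_outpatient = 229,
    cost_psore_outpatient = 1803,
    cost_inpatient_stay = 17985,
    discount_rate_annual = 0.03,
    horizon_months = 60,
    cohort_size = 10000,
    death_conversion = c("compound", "simple"),
    outpatient_cost_scope = c("all", "nonhospitalized")) {
  inputs <- structure(
    list(groups = groups, p_death_annual = p_death_annual,
         stays_per_hosp_year = stays_per_hosp_year,
         cost_uti_outpatient = cost_uti_outpatient,
         cost_psore_outpatient = cost_psore_outpatient,
         cost_inpatient_stay = cost_inpatient_stay,
         discount_rate_annual = discount_rate_annual,
         horizon_months = horizon_months, cohort_size = cohort_size,
         death_conversion = match.arg(death_conversion),
         outpatient_cost_scope = match.arg(outpatient_cost_scope)),
    class = "model_inputs")
  validate_inputs(inputs)
}

#' Validate a `model_inputs` object
#'
#' @param inputs A `model_inputs` object (or a plain list with the same
#'   structure, e.g. after programmatic modification).
#' @return The validated object, invisibly classed `model_inputs`.
#' @export
validate_inputs <- function(inputs) {
  for (g in c("non_ambulatory", "ambulatory")) {
    if (is.null(inputs$groups[[g]])) abort("missing inputs for group '%s'", g)
    for (nm in c("p_uti", "p_psore", "p_hosp", "cond_hosp_uti",
                 "cond_hosp_psore")) {
      check_prob(inputs$groups[[g]][[nm]], paste(g, nm, sep = "."))
    }
  }
  check_prob(inputs$p_death_annual, "p_death_annual")
  check_nonneg(inputs$stays_per_hosp_year, "stays_per_hosp_year")
  if (inputs$stays_per_hosp_year <= 0) abort("'stays_per_hosp_year' must be positive")
  for (nm in c("cost_uti_outpatient", "cost_psore_outpatient",
               "cost_inpatient_stay")) {
    check_nonneg(inputs[[nm]], nm)
  }
  if (inputs$discount_rate_annual < 0) abort("'discount_rate_annual' must be >= 0")
  h <- inputs$horizon_months
  if (h < 1 || h %% 12 != 0) abort("'horizon_months' must be a positive multiple of 12")
  if (inputs$cohort_size <= 0) abort("'cohort_size' must be positive")
  class(inputs) <- "model_inputs"
  invisible(inputs)
}

#' @export
print.model_inputs <- function(x, ...) {
  cat("Markov model inputs:", x$cohort_size, "persons,",
      x$horizon_months, "monthly cycles, discount",
      sprintf("%.1f%%/yr\n", 100 * x$discount_rate_annual))
  for (g in names(x$groups)) {
    gg <- x$groups[[g]]
    cat(sprintf("  %-15s UTI %.1f%%->%.1f%%  psore %.1f%%->%.1f%%  hosp %.1f%%->%.1f%%\n",
                g, 100 * gg$p_uti[["y1"]], 100 * gg$p_uti[["y5"]],
                100 * gg$p_psore[["y1"]], 100 * gg$p_psore[["y5"]],
                100 * gg$p_hosp[["y1"]], 100 * gg$p_hosp[["y5"]]))
  }
  invisible(x)
}

# ---- run configuration ------------------------------------------------------

#' Read, validate and write a pipeline configuration
#'
#' The configuration is a YAML file with sections `seed`, `stages`, `synth`
#' (overrides for [synth_params()]), `model` (overrides for
#' [model_inputs()]), and `psa` (`n_iterations`, `rel_width`, `cost_ci`, or
#' an explicit `distributions` list of parameter/kind/point/ci entries).
#' Every probability field is validated to \[0, 1\] with an error naming the
#' offending key.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config()` returns the validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$stages <- config$stages %||% c("synth", "adjust", "markov", "oneway", "psa")
  bad <- setdiff(config$stages, c("synth", "adjust", "markov", "oneway", "psa"))
  if (length(bad)) abort("unknown stage(s): %s", paste(bad, collapse = ", "))
  walk <- function(x, path) {
    leaf <- sub(".*\\.", "", path)
    if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], paste(path, nm, sep = "."))
    } else if (grepl("^(p_|prob|cond_|rate_non)", leaf) && is.numeric(x)) {
      if (anyNA(x) || any(x < 0) || any(x > 1)) {
        abort("config key '%s' must be a probability in [0, 1]", sub("^\\.", "", path))
      }
    }
  }
  for (sec in intersect(c("synth", "model"), names(config))) {
    walk(config[[sec]], sec)
  }
  config
}

# Build model_inputs from the config's `model` section (flat overrides of
# model_inputs() arguments; `groups` may override individual fields).
config_model_inputs <- function(config) {
  m <- config$model %||% list()
  inputs <- model_inputs()
  for (nm in intersect(names(m), setdiff(names(inputs), "groups"))) {
    inputs[[nm]] <- m[[nm]]
  }
  for (g in intersect(names(m$groups %||% list()), names(inputs$groups))) {
    for (nm in names(m$groups[[g]])) {
      v <- unlist(m$groups[[g]][[nm]])
      if (!setequal(names(v), c("y1", "y5"))) {
        abort("config model.groups.%s.%s must have y1 and y5", g, nm)
      }
      inputs$groups[[g]][[nm]] <- v[c("y1", "y5")]
    }
  }
  validate_inputs(inputs)
}

config_synth_params <- function(config) {
  s <- config$synth %||% list()
  s <- s[intersect(names(s), names(formals(synth_params)))]
  if (is.null(s$seed)) s$seed <- stage_seed(config$seed %||% 1L, "synth")
  do.call(synth_params, s)
}
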