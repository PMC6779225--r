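# Five-state monthly-cycle Markov cohort engine.
#
# A closed cohort is projected as expected-value (cohort, not individual)
# masses over monthly cycles. In each cycle a member can experience UTI
# (with or without hospitalization), pressure sore (with or without
# hospitalization), hospitalization for another cause, no complication, or
# death. Death is the only absorbing transition; event tallies are expected
# counts of the at-risk alive mass and are not mutually exclusive, which is
# what lets the marginal annual probabilities drive per-category
# person-totals directly.

#' Linear interpolation of an annual probability across projection years
#'
#' Years 2-4 are interpolated linearly between the year-1 and year-5 values.
#'
#' @param p_y1,p_y5 Annual probabilities at projection years 1 and 5.
#' @param year Integer year(s) in 1..5.
#' @return Interpolated annual probability, always between the two inputs.
#' @examples
#' interpolate_annual(0.331, 0.377, 3) # 0.354
#' @export
interpolate_annual <- function(p_y1, p_y5, year) {
  check_prob(p_y1, "p_y1"); check_prob(p_y5, "p_y5")
  if (any(year < 1 | year > 5 | year != round(year))) {
    abort("'year' must be an integer in 1..5")
  }
  p_y1 + (year - 1) * (p_y5 - p_y1) / 4
}

#' Convert an annual probability to a monthly probability
#'
#' Compound-probability conversion `1 - (1 - p)^(1/12)`, so that twelve
#' independent monthly draws reproduce the annual probability exactly.
#'
#' @param p_annual Annual probability.
#' @param method `"compound"` (default) or `"simple"` (`p/12`).
#' @return Monthly probability.
#' @export
annual_to_monthly <- function(p_annual, method = c("compound", "simple")) {
  method <- match.arg(method)
  check_prob(p_annual, "p_annual")
  if (method == "compound") 1 - (1 - p_annual)^(1 / 12) else p_annual / 12
}

#' End-of-cycle discount factor
#'
#' @param month Cycle index (months since model entry), `>= 1`.
#' @param rate_annual Annual discount rate, `>= 0`.
#' @return `(1 + rate)^(-month/12)`; 1 when the rate is 0.
#' @export
discount_factor <- function(month, rate_annual) {
  if (any(month < 1)) abort("'month' must be >= 1")
  if (rate_annual < 0) abort("'rate_annual' must be >= 0")
  (1 + rate_annual)^(-month / 12)
}

#' Project one ambulation group through the Markov cohort model
#'
#' Deterministic expected-value projection. Each cycle, deaths are removed
#' at cycle start (monthly mortality from the compound conversion of the
#' annual death probability); event masses accrue as the at-risk alive mass
#' times one twelfth of that year's interpolated annual probability, so a
#' full year of cycles tallies `alive x p_annual` persons with each event.
#' All-cause hospitalization is decomposed into UTI-associated and
#' pressure-sore-associated parts via the conditional hospitalization
#' probabilities, with the remainder hospitalized for other causes. Costs
#' accrue per event (outpatient UTI and pressure-sore treatment) and per
#' hospitalized person-year (`stays_per_hosp_year` inpatient stays), and are
#' discounted with end-of-cycle monthly factors.
#'
#' @param inputs A [model_inputs()] object.
#' @param group `"non_ambulatory"` or `"ambulatory"`.
#' @return A data frame of class `cohort_trace`, one row per cycle, with the
#'   alive mass, deaths, expected event masses, and (discounted) costs.
#'   Attributes `group` and `inputs` carry the provenance.
#' @export
run_cohort <- function(inputs, group = c("non_ambulatory", "ambulatory")) {
  inputs <- validate_inputs(inputs)
  group <- match.arg(group)
  g <- inputs$groups[[group]]
  H <- inputs$horizon_months
  t <- seq_len(H)
  year <- ceiling(t / 12)

  p_dm <- annual_to_monthly(inputs$p_death_annual, inputs$death_conversion)
  alive_start <- inputs$cohort_size * (1 - p_dm)^(t - 1)
  deaths <- alive_start * p_dm
  at_risk <- alive_start - deaths

  ann <- function(p) interpolate_annual(p[["y1"]], p[["y5"]], year)
  uti <- at_risk * ann(g$p_uti) / 12
  psore <- at_risk * ann(g$p_psore) / 12
  hosp_any <- at_risk * ann(g$p_hosp) / 12
  uti_hosp <- uti * ann(g$cond_hosp_uti)
  psore_hosp <- psore * ann(g$cond_hosp_psore)
  hosp_other <- hosp_any - uti_hosp - psore_hosp
  if (any(hosp_other < -1e-9)) {
    abort(paste0("conditional hospitalization exceeds all-cause ",
                 "hospitalization in year %d"),
          min(year[hosp_other < -1e-9]))
  }
  hosp_other <- pmax(hosp_other, 0)

  if (inputs$outpatient_cost_scope == "all") {
    uti_outp <- uti; psore_outp <- psore
  } else {
    uti_outp <- uti - uti_hosp; psore_outp <- psore - psore_hosp
  }
  cost <- uti_outp * inputs$cost_uti_outpatient +
    psore_outp * inputs$cost_psore_outpatient +
    hosp_any * inputs$stays_per_hosp_year * inputs$cost_inpatient_stay
  df <- discount_factor(t, inputs$discount_rate_annual)

  trace <- data.frame(cycle = t, year = year, alive_start = alive_start,
                      deaths = deaths, at_risk = at_risk, uti = uti,
                      psore = psore, hosp_any = hosp_any,
                      uti_hosp = uti_hosp, psore_hosp = psore_hosp,
                      hosp_other = hosp_other, cost = cost,
                      cost_discounted = cost * df)
  structure(trace, group = group, inputs = inputs,
            class = c("cohort_trace", "data.frame"))
}

#' Summarize a cohort trace into five-year group results
#'
#' Person-event totals are sums of per-cycle expected event masses; the
#' average cost is total discounted cost divided by the cohort size; the
#' multi-year-average annual probabilities are unweighted means of the
#' interpolated annual values.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param inputs The [model_inputs()] used (defaults to the trace attribute).
#' @return An object of class `group_results`.
#' @export
summarize_cohort <- function(trace, inputs = attr(trace, "inputs")) {
  stopifnot(inherits(trace, "cohort_trace"))
  group <- attr(trace, "group")
  g <- inputs$groups[[group]]
  years <- floor(inputs$horizon_months / 12)
  if (inputs$horizon_months != 60) {
    warning(sprintf("horizon is %d months; annual averages computed over %d years",
                    inputs$horizon_months, years), call. = FALSE)
  }
  yrs <- seq_len(min(years, 5))
  avg <- function(p) mean(interpolate_annual(p[["y1"]], p[["y5"]], yrs))
  structure(list(
    group = group, cohort_size = inputs$cohort_size,
    average_cost = sum(trace$cost_discounted) / inputs$cohort_size,
    total_cost_discounted = sum(trace$cost_discounted),
    total_cost_undiscounted = sum(trace$cost),
    persons = c(uti_all = sum(trace$uti),
                uti_hospitalized = sum(trace$uti_hosp),
                psore_all = sum(trace$psore),
                psore_hospitalized = sum(trace$psore_hosp),
                hosp_any = sum(trace$hosp_any),
                hosp_other = sum(trace$hosp_other),
                deaths = sum(trace$deaths)),
    annual_prob_avg = c(uti = avg(g$p_uti), psore = avg(g$p_psore),
                        hosp_any = avg(g$p_hosp),
                        death = inputs$p_death_annual)),
    class = "group_results")
}

#' @export
print.group_results <- function(x, ...) {
  cat(sprintf("Group: %s (cohort %s)\n", x$group,
              format(x$cohort_size, big.mark = ",")))
  cat(sprintf("  Average discounted cost per person: $%s\n",
              format(round_half_up(x$average_cost), big.mark = ",")))
  p <- round_half_up(x$persons)
  for (nm in names(p)) {
    cat(sprintf("  %-20s %s\n", nm, format(p[[nm]], big.mark = ",")))
  }
  a <- x$annual_prob_avg
  cat(sprintf("  Avg annual prob: UTI %.1f%%, psore %.1f%%, hosp %.1f%%, death %.1f%%\n",
              100 * a[["uti"]], 100 * a[["psore"]], 100 * a[["hosp_any"]],
              100 * a[["death"]]))
  invisible(x)
}
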