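# One-way (tornado) and probabilistic sensitivity analyses.

#' Fit a sampling distribution to a point estimate with 95% CI bounds
#'
#' Beta (for probabilities) and gamma (for positive quantities such as unit
#' costs) distributions are fitted by matching the mean to the point
#' estimate and solving, by monotone root bisection on the concentration
#' (beta) or shape (gamma), for the parameterization whose central 95%
#' interval width matches the supplied bounds. `"fixed"` yields a degenerate
#' distribution.
#'
#' @param parameter Parameter name: a dotted path into [model_inputs()],
#'   e.g. `"groups.non_ambulatory.p_uti.y1"` or `"cost_inpatient_stay"`.
#' @param point Point estimate (the distribution mean).
#' @param ci_low,ci_high 95% interval bounds bracketing the point.
#' @param kind `"beta"`, `"gamma"` or `"fixed"`.
#' @return An object of class `param_distribution` with fitted shape
#'   parameters.
#' @export
fit_distribution <- function(parameter, point, ci_low, ci_high,
                             kind = c("beta", "gamma", "fixed")) {
  kind <- match.arg(kind)
  if (kind != "fixed" && !(ci_low <= point && point <= ci_high)) {
    abort("bounds (%g, %g) do not bracket the point %g for '%s'",
          ci_low, ci_high, point, parameter)
  }
  shape <- switch(kind,
    fixed = list(),
    beta = {
      if (point <= 0 || point >= 1 || ci_low < 0 || ci_high > 1) {
        abort("beta is only valid for probabilities strictly inside (0, 1): '%s'",
              parameter)
      }
      w <- ci_high - ci_low
      if (w <= 0) abort("zero-width interval for beta parameter '%s'", parameter)
      f <- function(log10k) {
        k <- 10^log10k
        # qbeta's precision warning at extreme concentrations is harmless here
        diff(suppressWarnings(
          stats::qbeta(c(0.025, 0.975), point * k, (1 - point) * k))) - w
      }
      root <- tryCatch(stats::uniroot(f, c(-2, 10), tol = 1e-12),
                       error = function(e) {
                         abort("cannot fit beta interval for '%s': %s",
                               parameter, conditionMessage(e))
                       })
      k <- 10^root$root
      list(shape1 = point * k, shape2 = (1 - point) * k)
    },
    gamma = {
      if (point <= 0) abort("gamma requires a positive point estimate: '%s'", parameter)
      w <- ci_high - ci_low
      if (w <= 0) abort("zero-width interval for gamma parameter '%s'", parameter)
      f <- function(log10a) {
        a <- 10^log10a
        diff(stats::qgamma(c(0.025, 0.975), shape = a, rate = a / point)) - w
      }
      root <- tryCatch(stats::uniroot(f, c(-2, 12), tol = 1e-12),
                       error = function(e) {
                         abort("cannot fit gamma interval for '%s': %s",
                               parameter, conditionMessage(e))
                       })
      a <- 10^root$root
      list(shape = a, rate = a / point)
    })
  structure(list(parameter = parameter, kind = kind, point = point,
                 ci_low = ci_low, ci_high = ci_high, shape = shape),
            class = "param_distribution")
}

#' Quantile function of a fitted parameter distribution
#'
#' @param dist A [fit_distribution()] object.
#' @param u Probabilities in \[0, 1\].
#' @return Parameter values at the given quantiles (the point estimate for
#'   `"fixed"`).
#' @export
q_param <- function(dist, u) {
  stopifnot(inherits(dist, "param_distribution"))
  switch(dist$kind,
         fixed = rep(dist$point, length(u)),
         beta = suppressWarnings(
           stats::qbeta(u, dist$shape$shape1, dist$shape$shape2)),
         gamma = stats::qgamma(u, shape = dist$shape$shape, rate = dist$shape$rate))
}

#' One-way sensitivity of the average cost to a single parameter
#'
#' Reruns the cohort model with one parameter set to its lower and upper
#' bounds, everything else at base case.
#'
#' @param inputs A [model_inputs()] object (base case).
#' @param parameter Dotted parameter path (see [fit_distribution()]). A
#'   character vector moves several paths to their bounds jointly (one
#'   tornado variable), e.g. the year-1 and year-5 values of one rate.
#' @param low,high Bound values (same length as `parameter`), `low <= high`.
#' @param group Ambulation group to evaluate.
#' @param label Display name for the entry; defaults to the common prefix of
#'   the paths.
#' @return One-row data frame of class `tornado_entry`: base cost, cost at
#'   each bound, percent change vs base, and the absolute swing.
#' @export
one_way <- function(inputs, parameter, low, high,
                    group = c("non_ambulatory", "ambulatory"),
                    label = NULL) {
  group <- match.arg(group)
  if (length(low) != length(parameter) || length(high) != length(parameter)) {
    abort("'low' and 'high' must match the length of 'parameter'")
  }
  if (any(low > high)) abort("'low' must be <= 'high' for '%s'", parameter[low > high][1])
  for (p in parameter) get_in(inputs, p)  # errors on unknown path
  cost_at <- function(v) {
    cur <- inputs
    for (j in seq_along(parameter)) cur <- set_in(cur, parameter[j], v[j])
    summarize_cohort(run_cohort(validate_inputs(cur), group))$average_cost
  }
  base <- summarize_cohort(run_cohort(inputs, group))$average_cost
  cl <- cost_at(low); ch <- cost_at(high)
  if (is.null(label)) {
    label <- if (length(parameter) == 1) parameter else
      sub("\\.(y1|y5)$", "", parameter[1])
  }
  structure(data.frame(parameter = label, group = group, base_cost = base,
                       cost_at_low = cl, cost_at_high = ch,
                       pct_change_low = 100 * (cl - base) / base,
                       pct_change_high = 100 * (ch - base) / base,
                       swing = abs(ch - cl), stringsAsFactors = FALSE),
            class = c("tornado_entry", "data.frame"))
}

#' Tornado analysis over a set of parameter bounds
#'
#' @param inputs Base-case [model_inputs()].
#' @param distributions List of [fit_distribution()] objects (their CI
#'   bounds are the tested bounds); `"fixed"` entries are skipped.
#' @param group Ambulation group.
#' @param couple_waves Treat the `y1` and `y5` distributions of the same
#'   rate as one tornado variable, moved to its bounds jointly (default;
#'   mirrors the wave coupling of [run_psa()]).
#' @return Data frame of [one_way()] entries sorted by decreasing swing.
#' @export
tornado <- function(inputs, distributions,
                    group = c("non_ambulatory", "ambulatory"),
                    couple_waves = TRUE) {
  group <- match.arg(group)
  dl <- Filter(function(d) d$kind != "fixed", distributions)
  paths <- vapply(dl, `[[`, "", "parameter")
  key <- if (couple_waves) sub("\\.(y1|y5)$", "", paths) else paths
  rows <- lapply(unique(key), function(k) {
    dd <- dl[key == k]
    one_way(inputs,
            vapply(dd, `[[`, "", "parameter"),
            vapply(dd, `[[`, 0, "ci_low"),
            vapply(dd, `[[`, 0, "ci_high"),
            group, label = k)
  })
  out <- do.call(rbind, rows)
  out[order(-out$swing), ]
}

#' Illustrative PSA distributions for the base-case inputs
#'
#' Beta distributions for each group's annual event probabilities (bounds a
#' fixed relative width around the point estimate, capped inside (0, 1)) and
#' a gamma distribution for the inpatient-stay cost. The registry CIs behind
#' the published analysis are not redistributable, so these bounds are
#' illustrative defaults; pass explicitly fitted distributions for real use.
#'
#' @param inputs A [model_inputs()] object.
#' @param rel_width Relative half-width of the probability bounds.
#' @param cost_ci Bounds for the inpatient-stay cost.
#' @return Named list of `param_distribution` objects.
#' @export
default_psa_distributions <- function(inputs, rel_width = 0.15,
                                      cost_ci = c(16000, 20000)) {
  dists <- list()
  for (g in c("non_ambulatory", "ambulatory")) {
    for (ev in c("p_uti", "p_psore", "p_hosp")) {
      for (w in c("y1", "y5")) {
        path <- paste("groups", g, ev, w, sep = ".")
        p <- get_in(inputs, path)
        lo <- max(1e-4, p * (1 - rel_width))
        hi <- min(0.999, p * (1 + rel_width))
        dists[[path]] <- fit_distribution(path, p, lo, hi, "beta")
      }
    }
  }
  dists[["cost_inpatient_stay"]] <-
    fit_distribution("cost_inpatient_stay", inputs$cost_inpatient_stay,
                     cost_ci[1], cost_ci[2], "gamma")
  dists
}

#' Probabilistic sensitivity analysis
#'
#' Each iteration samples every distributed parameter, reruns both groups'
#' cohorts, and records the average cost per person and the cost difference
#' (ambulatory minus non-ambulatory). Year-1 and year-5 distributions for
#' the same parameter are sampled at a shared quantile by default so the
#' within-parameter trend direction is preserved. Sampled probabilities
#' falling outside \[0, 1\] are rejected and redrawn (bounded; a rejection
#' rate above 1% raises a warning).
#'
#' @param inputs Base-case [model_inputs()].
#' @param distributions List of [fit_distribution()] objects.
#' @param n_iterations Number of simulations.
#' @param seed Integer seed; the PSA is bitwise reproducible given it.
#' @param couple_waves Share one quantile draw between the `y1` and `y5`
#'   distributions of the same parameter.
#' @return An object of class `psa_result` with the per-iteration results.
#' @export
run_psa <- function(inputs, distributions, n_iterations = 1000, seed = 1,
                    couple_waves = TRUE) {
  if (n_iterations < 1) abort("'n_iterations' must be >= 1")
  set.seed(as.integer(seed))
  names(distributions) <- vapply(distributions, `[[`, "", "parameter")
  key <- if (couple_waves) sub("\\.(y1|y5)$", "", names(distributions)) else
    names(distributions)
  ukeys <- unique(key)
  is_prob <- grepl("^groups\\.|^p_|prob", names(distributions))
  rejections <- 0L
  res <- matrix(NA_real_, n_iterations, 3,
                dimnames = list(NULL, c("cost_non_ambulatory",
                                        "cost_ambulatory", "cost_difference")))
  for (i in seq_len(n_iterations)) {
    u <- stats::runif(length(ukeys))
    names(u) <- ukeys
    cur <- inputs
    for (j in seq_along(distributions)) {
      d <- distributions[[j]]
      v <- q_param(d, u[[key[j]]])
      tries <- 0L
      while (is_prob[j] && (v < 0 || v > 1) && tries < 100L) {
        v <- q_param(d, stats::runif(1))
        rejections <- rejections + 1L
        tries <- tries + 1L
      }
      cur <- set_in(cur, d$parameter, v)
    }
    cur <- validate_inputs(cur)
    cna <- summarize_cohort(run_cohort(cur, "non_ambulatory"))$average_cost
    cam <- summarize_cohort(run_cohort(cur, "ambulatory"))$average_cost
    res[i, ] <- c(cna, cam, cam - cna)
  }
  rate <- rejections / (n_iterations * max(1, length(distributions)))
  if (rate > 0.01) {
    warning(sprintf("PSA rejection rate %.1f%% exceeds 1%%", 100 * rate),
            call. = FALSE)
  }
  structure(list(iterations = data.frame(iter = seq_len(n_iterations), res),
                 n_iterations = n_iterations, seed = as.integer(seed),
                 rejections = rejections),
            class = "psa_result")
}

psa_histogram_edges <- function() seq(-60000, 60000, by = 10000)

#' Summarize a PSA: cost quantiles and difference histogram
#'
#' Quantiles (minimum, 25th percentile, median, mean, 75th percentile,
#' maximum) of the per-person cost for each group and of the difference, and
#' a histogram of the cost difference in $10,000-wide left-closed,
#' right-open bins from below -$60,000 to above +$60,000. Displayed
#' percentages are rounded half-up to integers; exact values are retained.
#'
#' @param result A [run_psa()] result.
#' @return List with `quantiles` (data frame) and `histogram` (data frame
#'   with frequency, percentage, cumulative percentage).
#' @export
summarize_psa <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  it <- result$iterations
  qs <- function(x) {
    c(minimum = min(x), p25 = unname(stats::quantile(x, 0.25)),
      median = stats::median(x), mean = mean(x),
      p75 = unname(stats::quantile(x, 0.75)), maximum = max(x))
  }
  quantiles <- data.frame(
    statistic = c("Minimum", "25th Percentile", "Median", "Mean",
                  "75th Percentile", "Maximum"),
    non_ambulatory = qs(it$cost_non_ambulatory),
    ambulatory = qs(it$cost_ambulatory),
    difference = qs(it$cost_difference),
    row.names = NULL, stringsAsFactors = FALSE)

  edges <- psa_histogram_edges()
  # findInterval: left-closed, right-open bins; 0 = below the first edge
  bin <- findInterval(it$cost_difference, edges)
  freq <- tabulate(bin + 1L, nbins = length(edges) + 1L)
  usd <- function(x) paste0(ifelse(x < 0, "-$", "$"),
                            formatC(abs(x), format = "d", big.mark = ","))
  labels <- c(sprintf("Less than %s", usd(edges[1])),
              sprintf("%s to %s", usd(edges[-length(edges)]), usd(edges[-1])),
              sprintf("More than %s", usd(edges[length(edges)])))
  pct_exact <- 100 * freq / result$n_iterations
  cum_exact <- cumsum(pct_exact)
  histogram <- data.frame(
    bin = labels,
    bin_low = c(-Inf, edges), bin_high = c(edges, Inf),
    frequency = freq,
    percentage = round_half_up(pct_exact),
    cumulative = round_half_up(cum_exact),
    pct_exact = pct_exact, cum_exact = cum_exact,
    stringsAsFactors = FALSE)
  list(quantiles = quantiles, histogram = histogram)
}
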