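# Result tables and the end-to-end pipeline driver.

usd_fmt <- function(x) paste0(ifelse(x < 0, "-$", "$"),
                              formatC(round_half_up(abs(x)), format = "d",
                                      big.mark = ","))
int_fmt <- function(x) formatC(round_half_up(x), format = "d", big.mark = ",")
pct_fmt <- function(x) sprintf("%.1f%%", 100 * x)

#' Render the base-case five-year results table
#'
#' One row per result quantity, one column per ambulation group; counts as
#' integers, probabilities to one decimal percent, costs to whole dollars.
#'
#' @param res_na,res_amb [summarize_cohort()] results for the non-ambulatory
#'   and ambulatory groups.
#' @return A character data frame.
#' @export
render_base_case_table <- function(res_na, res_amb) {
  row <- function(label, f, na_v, am_v) {
    data.frame(variable = label, non_ambulatory = f(na_v),
               ambulatory = f(am_v), stringsAsFactors = FALSE)
  }
  p <- function(r, k) r$persons[[k]]
  a <- function(r, k) r$annual_prob_avg[[k]]
  rbind(
    row("Population size", int_fmt, res_na$cohort_size, res_amb$cohort_size),
    row("Average healthcare cost", usd_fmt, res_na$average_cost,
        res_amb$average_cost),
    row("Urinary tract infection, all", int_fmt, p(res_na, "uti_all"),
        p(res_amb, "uti_all")),
    row("Urinary tract infection, hospitalized", int_fmt,
        p(res_na, "uti_hospitalized"), p(res_amb, "uti_hospitalized")),
    row("Pressure sore, all", int_fmt, p(res_na, "psore_all"),
        p(res_amb, "psore_all")),
    row("Pressure sore, hospitalized", int_fmt,
        p(res_na, "psore_hospitalized"), p(res_amb, "psore_hospitalized")),
    row("Hospitalized, other causes", int_fmt, p(res_na, "hosp_other"),
        p(res_amb, "hosp_other")),
    row("Death", int_fmt, p(res_na, "deaths"), p(res_amb, "deaths")),
    row("Annual probability (5-year average): urinary tract infection",
        pct_fmt, a(res_na, "uti"), a(res_amb, "uti")),
    row("Annual probability (5-year average): pressure sore", pct_fmt,
        a(res_na, "psore"), a(res_amb, "psore")),
    row("Annual probability (5-year average): hospitalization, all-cause",
        pct_fmt, a(res_na, "hosp_any"), a(res_amb, "hosp_any")),
    row("Annual probability (5-year average): death", pct_fmt,
        a(res_na, "death"), a(res_amb, "death")))
}

#' Render PSA summary tables
#'
#' `render_psa_quantile_table()` formats the per-group cost quantiles;
#' `render_psa_histogram_table()` formats the cost-difference histogram.
#'
#' @param psa_summary A [summarize_psa()] result.
#' @return A character data frame.
#' @export
render_psa_quantile_table <- function(psa_summary) {
  q <- psa_summary$quantiles
  data.frame(Value = q$statistic,
             non_ambulatory = usd_fmt(q$non_ambulatory),
             ambulatory = usd_fmt(q$ambulatory),
             stringsAsFactors = FALSE)
}

#' @rdname render_psa_quantile_table
#' @export
render_psa_histogram_table <- function(psa_summary) {
  h <- psa_summary$histogram
  data.frame(`Cost Difference` = h$bin, Frequency = h$frequency,
             Percentage = sprintf("%d%%", h$percentage),
             Cumulative = sprintf("%d%%", h$cumulative),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages in order (synthetic cohort, logistic
#' adjustment, Markov base case for both groups, one-way and probabilistic
#' sensitivity analyses), writing every artifact under `out_dir` along with
#' a run log and a JSON manifest listing each output file with its MD5
#' content hash. Identical configuration and seed give identical hashes.
#'
#' @param config Configuration list (see [read_config()]) or a path to a
#'   YAML configuration file.
#' @param out_dir Output directory, created if needed.
#' @param seed Optional override of the config seed.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir = "results", seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(obj, name, writer) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  wcsv <- function(x, p) utils::write.csv(x, p, row.names = FALSE)
  wjson <- function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                               digits = NA, pretty = TRUE)
  stages <- config$stages
  cohort <- NULL
  inputs <- config_model_inputs(config)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }

  if ("synth" %in% stages) {
    run_stage("synth", {
      cohort <- generate_cohort(config_synth_params(config))
      emit(cohort, "cohort.csv", function(x, p) write_cohort(x, p))
      cohort <<- cohort
    })
  }
  if ("adjust" %in% stages) {
    run_stage("adjust", {
      if (is.null(cohort)) {
        path <- config$paths$cohort_csv %||%
          abort("adjust stage needs a cohort: run synth or set paths.cohort_csv")
        cohort <<- read_cohort(path)
      }
      adj <- adjust_cohort(cohort, means = config$adjust_means %||% "pooled")
      emit(adj$table, "adjusted_fits.csv", wcsv)
      if (isTRUE(config$use_adjusted)) {
        inputs <<- as_model_inputs(adj$table, inputs)
      }
    })
  }
  results <- NULL
  if ("markov" %in% stages) {
    run_stage("markov", {
      results <- lapply(c(non_ambulatory = "non_ambulatory",
                          ambulatory = "ambulatory"), function(g) {
        tr <- run_cohort(inputs, g)
        emit(tr, paste0("trace_", g, ".csv"), wcsv)
        summarize_cohort(tr)
      })
      emit(lapply(results, unclass), "group_results.json", wjson)
      emit(render_base_case_table(results$non_ambulatory, results$ambulatory),
           "base_case_table.csv", wcsv)
      results <<- results
    })
  }
  dists <- NULL
  if (any(c("oneway", "psa") %in% stages)) {
    dists <- config_psa_distributions(config, inputs)
  }
  if ("oneway" %in% stages) {
    run_stage("oneway", {
      for (g in c("non_ambulatory", "ambulatory")) {
        emit(tornado(inputs, dists, g), paste0("tornado_", g, ".csv"), wcsv)
      }
    })
  }
  if ("psa" %in% stages) {
    run_stage("psa", {
      psa <- run_psa(inputs, dists,
                     n_iterations = config$psa$n_iterations %||% 1000,
                     seed = stage_seed(config$seed, "psa"))
      emit(psa$iterations, "psa_iterations.csv", wcsv)
      ps <- summarize_psa(psa)
      emit(ps$quantiles, "psa_quantiles.csv", wcsv)
      emit(ps$histogram, "psa_difference_histogram.csv", wcsv)
      emit(render_psa_quantile_table(ps), "psa_quantile_table.csv", wcsv)
      emit(render_psa_histogram_table(ps), "psa_histogram_table.csv", wcsv)
    })
  } else if ("markov" %in% stages) {
    message("PSA stage not requested; PSA tables omitted")
  }

  cfg_hash <- unname(tools::md5sum(
    write_config(config, file.path(out_dir, "run_config.yaml"))))
  outputs <- c(outputs, file.path(out_dir, "run_config.yaml"))
  log_lines <- c(sprintf("ambucost %s",
                         as.character(utils::packageVersion("ambucost"))),
                 sprintf("seed: %d", config$seed),
                 sprintf("config_hash: %s", cfg_hash),
                 sprintf("stages: %s", paste(stages, collapse = ", ")),
                 if (!"psa" %in% stages) "psa: omitted")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ambucost")),
    seed = config$seed, config_hash = cfg_hash,
    psa_omitted = !"psa" %in% stages,
    files = lapply(outputs, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  wjson(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# PSA distribution set from the config `psa` section: explicit
# `distributions` entries, else illustrative defaults around the inputs.
config_psa_distributions <- function(config, inputs) {
  sec <- config$psa %||% list()
  if (!is.null(sec$distributions)) {
    lapply(sec$distributions, function(d) {
      fit_distribution(d$parameter,
                       d$point %||% get_in(inputs, d$parameter),
                       d$ci_low, d$ci_high, d$kind)
    })
  } else {
    default_psa_distributions(inputs,
                              rel_width = sec$rel_width %||% 0.15,
                              cost_ci = unlist(sec$cost_ci %||%
                                                 c(16000, 20000)))
  }
}
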