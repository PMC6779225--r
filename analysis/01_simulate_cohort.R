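#!/usr/bin/env Rscript
# Stage 1: simulate a registry-style cohort of adults with thoracic spinal
# cord injury and classify ambulatory ability from the three mobility items.
# Writes results/cohort.csv and prints the group descriptives the later
# stages build on.

suppressPackageStartupMessages(library(ambucost))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 20260921L

dir.create("results", showWarnings = FALSE)
params <- synth_params(n_patients = 20000, seed = seed)
cohort <- generate_cohort(params)
validate_outcomes(cohort)
write_cohort(cohort, "results/cohort.csv")

cls <- classify_ambulation(cohort$walk_150ft, cohort$walk_one_block,
                           cohort$climb_one_flight)
cat(sprintf("Simulated %d patients (seed %d): %.1f%% non-ambulatory, %.1f%% ambulatory, %.1f%% excluded (partial ability)\n",
            nrow(cohort), seed, 100 * mean(cls == "non_ambulatory"),
            100 * mean(cls == "ambulatory"), 100 * mean(cls == "excluded")))
lab <- c(uti_y1 = "UTI", psore_y1 = "Pressure sore", hosp_any_y1 = "Hospitalization")
for (col in names(lab)) {
  cat(sprintf("  Year-1 %-16s non-ambulatory %.1f%%, ambulatory %.1f%%\n",
              paste0(lab[[col]], ":"),
              100 * mean(cohort[[col]][cls == "non_ambulatory"]),
              100 * mean(cohort[[col]][cls == "ambulatory"])))
}
cat("Wrote results/cohort.csv\n")
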