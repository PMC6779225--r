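#!/usr/bin/env Rscript
# Stage 4: sensitivity analyses. One-way (tornado) analysis moves each rate
# (years 1 and 5 jointly) and the inpatient-stay cost to its interval
# bounds; the probabilistic sensitivity analysis samples all distributed
# parameters over 1,000 simulations and summarizes per-person cost by group
# and the ambulatory-minus-non-ambulatory difference. The registry CI
# bounds behind the published analysis are not redistributable, so the
# distributions here use the package's illustrative defaults (+/-15%
# relative bounds on probabilities; $16,000-$20,000 on the inpatient cost).

suppressPackageStartupMessages(library(ambucost))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 20260921L
dir.create("results", showWarnings = FALSE)

inputs <- model_inputs()
dists <- default_psa_distributions(inputs)

for (g in c("non_ambulatory", "ambulatory")) {
  tor <- tornado(inputs, dists, g)
  write.csv(tor, sprintf("results/tornado_%s.csv", g), row.names = FALSE)
  cat(sprintf("\nTornado, %s group (base $%s per person):\n", g,
              format(round(tor$base_cost[1]), big.mark = ",")))
  for (i in seq_len(nrow(tor))) {
    cat(sprintf("  %-42s %+6.1f%% to %+6.1f%%\n", tor$parameter[i],
                tor$pct_change_low[i], tor$pct_change_high[i]))
  }
}

psa <- run_psa(inputs, dists, n_iterations = 1000, seed = seed)
write.csv(psa$iterations, "results/psa_iterations.csv", row.names = FALSE)
s <- summarize_psa(psa)
write.csv(s$quantiles, "results/psa_quantiles.csv", row.names = FALSE)
write.csv(s$histogram, "results/psa_difference_histogram.csv", row.names = FALSE)
write.csv(render_psa_quantile_table(s), "results/psa_quantile_table.csv",
          row.names = FALSE)
write.csv(render_psa_histogram_table(s), "results/psa_histogram_table.csv",
          row.names = FALSE)

cat(sprintf("\nPSA (%d simulations, seed %d): cost per person\n",
            psa$n_iterations, seed))
print(render_psa_quantile_table(s), row.names = FALSE)
cat(sprintf("\nAmbulatory costs were lower in %.0f%% of simulations.\n",
            100 * mean(psa$iterations$cost_difference < 0)))
cat("Wrote results/tornado_*.csv and results/psa_*.csv\n")
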