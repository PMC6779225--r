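# Example pipeline configuration: simulate a cohort, fit the adjustment
# models, run the base-case Markov projection for both groups, and run both
# sensitivity analyses. Omitted model fields take the base-case defaults.
seed: 1
stages: [synth, adjust, markov, oneway, psa]
synth:
  n_patients: 5000
model:
  discount_rate_annual: 0.03
  cohort_size: 10000
  horizon_months: 60
psa:
  n_iterations: 1000
  rel_width: 0.15
  cost_ci: [16000, 20000]
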