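---
title: "Methods: a Markov cohort model of ambulation-related complication costs in spinal cord injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of ambulation-related complication costs in spinal cord injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambucost)
```

## The question and the model

Adults with traumatic thoracic spinal cord injury (SCI) who regain the
ability to walk experience fewer secondary complications — urinary tract
infections (UTI), pressure sores, and hospitalizations — than those who
remain non-ambulatory. `ambucost` implements a decision-analytic pipeline
that quantifies that difference in five-year complication burden and
medical cost:

1. **Classification.** Patients are classified from three self-reported
   mobility items (walk 150 feet, walk one block, climb one flight of
   stairs): all three → *ambulatory*; none → *non-ambulatory*; a partial
   pattern → excluded from the comparison.
2. **Adjustment.** Each complication at each follow-up wave (years 1 and 5
   post-injury) is regressed on the ambulatory indicator plus age, sex,
   marital status, employment, ASIA impairment grade, and injury level
   (T1–T6 vs T7–T12). The exponentiated ambulation coefficient is the
   covariate-adjusted odds ratio; evaluating the inverse logit of the fitted
   linear predictor at covariate means with the indicator at 0/1 gives the
   adjusted annual probability per group.
3. **Projection.** A five-state Markov cohort model (UTI ± hospitalization,
   pressure sore ± hospitalization, other-cause hospitalization, no
   complication, death) projects a closed cohort of 10,000 per group over 60
   monthly cycles, accruing discounted costs.
4. **Sensitivity.** One-way (tornado) analysis at interval bounds, and a
   probabilistic sensitivity analysis (PSA) sampling all distributed
   parameters.

Because the registry that motivates the pipeline (patient-level SCI
follow-up data) is not publicly deposited, the package ships a synthetic
cohort generator that emulates its structure; everything downstream of the
generator is the same code a real extract would flow through.

## The Markov engine

### States and accounting

Death is the only absorbing transition: the alive mass declines by the
monthly mortality probability each cycle, and deaths are removed at cycle
start before events accrue. The complication tallies are *expected person
counts of the at-risk alive mass*, not mutually exclusive state occupancies:
a cohort member can contribute to the UTI and the hospitalization tally in
the same year. This accounting is what allows marginal annual probabilities
(one per complication) to drive per-category person-totals directly; a
mutually exclusive five-way split would require joint probabilities the
data do not provide.

Annual probabilities are specified at projection years 1 and 5; years 2–4
are linearly interpolated,

$$p(y) = p_1 + (y-1)\,\frac{p_5 - p_1}{4}, \qquad y = 1,\dots,5 .$$

Within a year, each monthly cycle accrues `at_risk × p(y)/12` persons with
each event, so a full year of cycles tallies `alive × p(y)` — the annual
probability read as "fraction of at-risk persons with ≥1 event that year"
(repeat events within a year are not counted, matching how the underlying
annual outcomes are ascertained). Mortality, by contrast, is a true monthly
transition and uses the compound conversion
$p_m = 1-(1-p)^{1/12}$ (a `simple` $p/12$ switch exists but is not the
default).

All-cause hospitalization is decomposed via conditional probabilities: the
UTI-associated tally is `uti × Pr(hosp | uti)`, the pressure-sore tally
analogously, and the remainder is other-cause. A configuration whose
conditional decomposition exceeds all-cause hospitalization in any year is
rejected with an error naming the year.

### Costs and discounting

Each UTI accrues the outpatient treatment cost ($229), each pressure sore
$1,803, and each all-cause hospitalized person-year accrues
`stays_per_hosp_year` (1.6) × the inpatient-stay cost ($17,985), spread per
cycle — all in 2016 USD. Outpatient costs apply to every event, hospitalized
or not (a `nonhospitalized`-only switch exists); hospitalized person-years
are costed identically regardless of cause. Cycle costs are discounted with
end-of-cycle monthly factors $(1+r)^{-t/12}$ at $r = 3\%$ per year; no
half-cycle correction is applied.

### Numerical conventions and degenerate inputs

The projection is a deterministic expected-value calculation: mass
conservation holds to 1e-9 and every result scales exactly linearly with
cohort size. A zero-probability configuration yields a constant alive mass
and zero cost; an annual death probability of 1 absorbs the full cohort in
the first cycle. The horizon must be a positive multiple of 12; summaries
over a horizon other than 60 months warn and average over the available
whole years.

### Calibrated defaults

Two base-case inputs are calibration choices rather than published values:

* **Year-5 conditional hospitalization fractions.** The published inputs
  give year-1 conditional hospitalization (16.8%/10.6% for UTI,
  19.1%/0% for pressure sore) but not year 5. The defaults (UTI 15.0%
  non-ambulatory / 3.0% ambulatory; pressure sore 20.5% / 0) were
  back-solved analytically so that, under linear interpolation of the
  conditional fraction, the five-year hospitalized-event subtotals
  approximate the published base-case results. They only affect the
  decomposition of hospitalizations by cause, not costs or all-cause
  totals, and are overridable.
* **Known input inconsistency.** The published five-year results report 746
  deaths and a 1.6% average annual death probability, but the stated input
  is a flat 1.5% annual probability, which implies ≈728 deaths. The
  mortality schedule behind the published figure is not fully specified;
  the package reports the model-implied values and does not force
  agreement.

## The adjustment stage

Logistic models are fitted by iteratively reweighted least squares
(`stats::glm.fit`, deviance tolerance 1e-12, ≤100 iterations). The package
re-derives the coefficient covariance from the final weights and reports an
explicit `converged` flag requiring the maximum absolute score at the
optimum to be below 1e-6 — far below any statistically meaningful scale, and
robustly attainable at realistic sample sizes. Apparent separation (extreme
coefficients or standard errors) clears the flag with a warning;
rank-deficient designs error, naming the offending column. Intervals and
p-values are Wald-type; profile likelihood would change nothing material at
these sample sizes and would be harder to verify against closed forms.

Adjusted probabilities are evaluated, by default, at **pooled** covariate
means: both groups share one mean vector and differ only through the group
indicator. The published base-case inputs are internally consistent with
exactly this convention — logit(0.733) + log(0.454) = logit(0.556) — which
cannot hold under group-specific means when the groups' covariate
distributions differ as strongly as they do here (ASIA grade in
particular). A `means = "group"` switch evaluates each group at its own
means instead. Patients with partial mobility ability and unknown ASIA
grade are removed before fitting; covariates are handled complete-case
(the generator produces complete covariates, and missing-data machinery is
out of scope).

## The synthetic cohort generator

The generator emulates the registry's *structure*, not any patient's data:

* **Covariates** are drawn independently within latent ambulation class
  from the published group-wise marginals (age truncated normal on
  [18, 90]; binary covariates Bernoulli; ASIA grade and injury level
  categorical). The joint distribution is not published, so independence is
  an explicit assumption — synthetic covariates will show less correlation
  (e.g. between ASIA grade and employment) than real registry data.
* **Class mix**: 18% ambulatory among classifiable patients; 15% of all
  patients have partial ability and are excluded by the classification
  rule (the published analysis reports only the classified sample, so the
  partial fraction is a realistic choice, not a published value). Year-5
  follow-up is retained with probability 0.76, matching the published
  1,340/1,753 wave ratio.
* **Outcomes** are Bernoulli under a logistic model whose ambulation
  coefficient is the log of the target adjusted odds ratio (defaults
  0.454/0.256 for UTI at years 1/5, 0.235/0.264 for pressure sore,
  0.585/0.567 for hospitalization) and whose ASIA-grade coefficients
  carry the confounding: they are what separates the large marginal rate
  gap (e.g. 75.7% vs 34.1% year-1 UTI) from the much smaller adjusted odds
  ratio. Intercepts are back-solved from target non-ambulatory rates at a
  reference covariate-mean vector — the non-ambulatory group's own means by
  default (`rate_reference = "group"`, so marginal group rates match the
  descriptive table), or pooled means (`rate_reference = "pooled"`, so the
  targets are recovered as adjusted-at-pooled-means probabilities, the
  scale on which the base-case model inputs are stated).
* **Hospitalization** sub-flags are drawn conditionally on their parent
  event; all-cause hospitalization is forced when a sub-flag fires and
  otherwise drawn from the residual other-cause probability, so the
  marginal hospitalization rate matches its logistic target exactly.
  Inpatient stays for hospitalized patients are `1 + Poisson(mean − 1)`
  (group means 1.7/1.4); days hospitalized are shifted negative binomial to
  reproduce the published overdispersion. UTI, pressure sore and
  hospitalization are conditionally independent given covariates — another
  stated simplification, as the registry's outcome correlations are not
  published.

Consequently, passing tests demonstrate that the *pipeline* recovers known
generating quantities (odds ratios, adjusted probabilities) from data with
this structure; they cannot certify behaviour under covariate or outcome
dependence patterns the generator does not emulate.

## Sensitivity analyses

**Distributions.** Probabilities get beta distributions, the inpatient cost
a gamma — the standard health-economics choices for [0, 1] and positive
quantities. Each is fitted by matching the mean to the point estimate and
bisecting on the concentration (beta) or shape (gamma) until the central
95% interval width matches the supplied bounds; the fitted mean equals the
point by construction. The published appendix of per-variable CI bounds is
not available, so the default bounds are illustrative (±15% relative on
probabilities; $16,000–$20,000 on the inpatient cost, the latter spanning
roughly ±11% around $17,985); they were fixed once, before any sensitivity
result was inspected, and real bounds can be supplied through the
configuration.

**Tornado.** Each variable is moved to its lower and upper bounds with all
else at base case. The year-1 and year-5 values of one rate are moved
jointly (one tornado variable) — treating them separately would split one
epidemiological quantity into two half-strength bars. Under the default
bounds the hospitalization rate dominates both groups' tornados, consistent
with hospitalization carrying ~90% of the cost.

**PSA.** Each of 1,000 iterations samples every distributed parameter and
reruns both groups. Year-1/year-5 distributions of the same rate share one
quantile draw (preserving the trend direction; a fully independent switch
exists); parameters are otherwise independent, and the death probability
and stays-per-year are held fixed, as the base case gives them no group
variation. Sampling is seeded and bitwise reproducible. Summaries follow
the published layout: per-group cost quantiles, and a histogram of the
ambulatory-minus-non-ambulatory difference in $10,000 left-closed,
right-open bins from below −$60,000 to above +$60,000, with half-up integer
rounding for display and exact values retained.

## Problem sizes used in the test suite

The shipped tests exercise the generator at 20,000 patients for rate
checks, 200 replicates of 1,700 patients (the registry's one-year sample
size) for CI coverage of the generating odds ratio, and 20 replicates of
10,000 for mean bias; the Markov engine always runs its full 10,000 × 60
configuration (it is a closed-form-speed calculation); PSA checks use
20–200 iterations, with the full 1,000 in the analysis scripts. These sizes
were chosen to give Monte-Carlo error comfortably inside the asserted
tolerances.

## Known limitations

* Costs cover the three modeled complication categories only; attendant
  care, equipment, medications and environmental modifications are out of
  scope, as is any payer-mix reimbursement adjustment.
* Mortality is a flat annual probability, not a life table, and does not
  differ by group.
* The synthetic generator's independence assumptions (covariates; outcomes
  given covariates; mobility items deterministic given class) understate
  real-data correlation.
* The five-year-average annual probabilities are unweighted means of the
  interpolated annual values; survival-weighted averaging would differ in
  the second decimal.
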