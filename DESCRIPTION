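Package: ambucost
Title: Markov Cohort Model of Ambulation-Related Complication Costs in
    Spinal Cord Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic pipeline estimating five-year medical
    complication burden and costs in adults with thoracic spinal cord
    injury, by ambulatory status. Provides a synthetic registry-style
    patient generator, covariate-adjusted logistic estimation of annual
    complication probabilities (urinary tract infection, pressure sore,
    all-cause hospitalization), a five-state monthly-cycle Markov cohort
    engine with linear interpolation of annual probabilities and
    discounted cost accumulation, and one-way (tornado) and probabilistic
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
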