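test_that("annual probabilities interpolate linearly between years 1 and 5", {
  expect_equal(interpolate_annual(0.331, 0.377, 3), 0.354)
  expect_equal(interpolate_annual(0.733, 0.624, 2), 0.70575)
  expect_equal(interpolate_annual(0.2, 0.2, 4), 0.2)
  # midpoint equals the arithmetic mean; result bounded by the inputs
  set.seed(4)
  for (i in 1:10) {
    p <- sort(runif(2))
    expect_equal(interpolate_annual(p[1], p[2], 3), mean(p))
    v <- interpolate_annual(p[1], p[2], 1:5)
    expect_true(all(v >= p[1] - 1e-15 & v <= p[2] + 1e-15))
  }
  expect_error(interpolate_annual(0.3, 0.4, 6), "1..5")
  expect_error(interpolate_annual(0.3, 0.4, 0), "1..5")
})

test_that("annual-to-monthly conversion compounds and round-trips", {
  expect_equal(annual_to_monthly(0), 0)
  expect_equal(annual_to_monthly(1), 1)
  expect_equal(annual_to_monthly(0.015), 1 - 0.985^(1 / 12), tolerance = 1e-12)
  set.seed(9)
  p <- runif(20)
  pm <- annual_to_monthly(p)
  expect_equal(1 - (1 - pm)^12, p, tolerance = 1e-12)
  expect_equal(annual_to_monthly(0.12, method = "simple"), 0.01)
  expect_error(annual_to_monthly(1.2), "probability")
  expect_error(annual_to_monthly(-0.1), "probability")
})

test_that("discount factors follow the end-of-cycle convention", {
  expect_equal(discount_factor(12, 0.03), 1 / 1.03, tolerance = 1e-12)
  expect_equal(discount_factor(24, 0.03), 1.03^-2, tolerance = 1e-12)
  expect_equal(discount_factor(37, 0), 1)
  expect_error(discount_factor(0, 0.03), ">= 1")
  expect_error(discount_factor(12, -0.01), ">= 0")
})

test_that("degenerate cohorts behave as closed-form limits", {
  zero <- toy_inputs()
  zero$groups$non_ambulatory[c("p_uti", "p_psore", "p_hosp")] <-
    lapply(1:3, function(i) c(y1 = 0, y5 = 0))
  zero$p_death_annual <- 0
  tr <- run_cohort(validate_inputs(zero), "non_ambulatory")
  expect_equal(tr$alive_start, rep(100, 12))
  expect_equal(sum(tr$cost), 0)
  # annual death probability 1: everyone dies in the first cycle
  dead <- toy_inputs()
  dead$p_death_annual <- 1
  tr <- run_cohort(validate_inputs(dead), "non_ambulatory")
  expect_equal(tr$deaths[1], 100)
  expect_equal(sum(tr$deaths) + (tr$alive_start[12] - tr$deaths[12]), 100,
               tolerance = 1e-9)
})

test_that("mass is conserved and results scale linearly with cohort size", {
  set.seed(31)
  for (i in 1:5) {
    inp <- model_inputs(cohort_size = 10000, p_death_annual = runif(1, 0, 0.2))
    g <- sample(c("non_ambulatory", "ambulatory"), 1)
    tr <- run_cohort(inp, g)
    # alive_start(t+1) = alive_start(t) - deaths(t); total mass conserved
    expect_equal(tr$alive_start[-1],
                 (tr$alive_start - tr$deaths)[-nrow(tr)], tolerance = 1e-9)
    expect_equal(sum(tr$deaths) + tr$alive_start[60] - tr$deaths[60],
                 inp$cohort_size, tolerance = 1e-9)
    expect_true(all(as.matrix(tr) >= -1e-12))
    inp2 <- inp; inp2$cohort_size <- 35000
    tr2 <- run_cohort(validate_inputs(inp2), g)
    expect_equal(tr2$uti, tr$uti * 3.5, tolerance = 1e-12)
    expect_equal(sum(tr2$cost_discounted), sum(tr$cost_discounted) * 3.5,
                 tolerance = 1e-9)
  }
})

test_that("event totals and costs respond monotonically to inputs", {
  inp <- model_inputs()
  base <- summarize_cohort(run_cohort(inp, "non_ambulatory"))
  up <- validate_inputs(
    ambucost:::set_in(inp, "groups.non_ambulatory.p_uti.y1", 0.9))
  res_up <- summarize_cohort(run_cohort(up, "non_ambulatory"))
  expect_gt(res_up$persons[["uti_all"]], base$persons[["uti_all"]])
  expect_gt(res_up$average_cost, base$average_cost)
  hi_disc <- inp; hi_disc$discount_rate_annual <- 0.08
  res_d <- summarize_cohort(run_cohort(validate_inputs(hi_disc),
                                       "non_ambulatory"))
  expect_lt(res_d$average_cost, base$average_cost)
  expect_equal(res_d$total_cost_undiscounted, base$total_cost_undiscounted,
               tolerance = 1e-9)
})

test_that("the engine matches a hand-enumerated two-cycle toy model", {
  inp <- toy_inputs()
  tr <- run_cohort(inp, "non_ambulatory")
  # independent spreadsheet-style enumeration of the first two cycles
  pdm <- 1 - (1 - 0.3)^(1 / 12)
  a1 <- 100
  d1 <- a1 * pdm
  r1 <- a1 - d1
  uti1 <- r1 * 0.4 / 12
  hosp1 <- r1 * 0.24 / 12
  cost1 <- uti1 * 229 + hosp1 * 1.6 * 17985
  a2 <- a1 - d1
  d2 <- a2 * pdm
  r2 <- a2 - d2
  uti2 <- r2 * 0.4 / 12
  hosp2 <- r2 * 0.24 / 12
  cost2 <- uti2 * 229 + hosp2 * 1.6 * 17985
  expect_equal(tr$alive_start[1:2], c(a1, a2), tolerance = 1e-10)
  expect_equal(tr$deaths[1:2], c(d1, d2), tolerance = 1e-10)
  expect_equal(tr$uti[1:2], c(uti1, uti2), tolerance = 1e-10)
  expect_equal(tr$hosp_any[1:2], c(hosp1, hosp2), tolerance = 1e-10)
  expect_equal(tr$cost[1:2], c(cost1, cost2), tolerance = 1e-10)
  expect_equal(tr$cost_discounted[1:2],
               c(cost1 * 1.03^(-1 / 12), cost2 * 1.03^(-2 / 12)),
               tolerance = 1e-10)
})

test_that("an impossible hospitalization decomposition is rejected by year", {
  inp <- toy_inputs()
  inp$groups$non_ambulatory$p_uti <- c(y1 = 0.9, y5 = 0.9)
  inp$groups$non_ambulatory$p_hosp <- c(y1 = 0.05, y5 = 0.05)
  inp$groups$non_ambulatory$cond_hosp_uti <- c(y1 = 0.9, y5 = 0.9)
  expect_error(run_cohort(validate_inputs(inp), "non_ambulatory"),
               "exceeds all-cause hospitalization in year 1")
})

test_that("summaries aggregate the trace and honour the discount identity", {
  inp <- model_inputs(discount_rate_annual = 0)
  res <- summarize_cohort(run_cohort(inp, "ambulatory"))
  expect_equal(res$total_cost_discounted, res$total_cost_undiscounted)
  # five-year-average annual probabilities are means of interpolated values
  expect_equal(unname(res$annual_prob_avg[["psore"]]),
               mean(interpolate_annual(0.104, 0.138, 1:5)))
  # sub-events never exceed their parent events
  expect_lte(res$persons[["uti_hospitalized"]], res$persons[["uti_all"]])
  expect_lte(res$persons[["psore_hospitalized"]], res$persons[["psore_all"]])
  short <- toy_inputs(horizon_months = 24)
  expect_warning(summarize_cohort(run_cohort(short, "non_ambulatory")),
                 "2 years")
})

test_that("invalid model inputs are rejected with named messages", {
  expect_error(model_inputs(p_death_annual = 1.5), "p_death_annual")
  expect_error(model_inputs(horizon_months = 50), "multiple of 12")
  expect_error(model_inputs(cost_inpatient_stay = -5), "cost_inpatient_stay")
  bad <- model_inputs()
  bad$groups$ambulatory$p_uti[["y1"]] <- 2
  expect_error(validate_inputs(bad), "ambulatory.p_uti")
})
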