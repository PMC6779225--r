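test_that("fitted distributions match their point estimate and interval", {
  fx <- fit_distribution("x", 0.5, 0.5, 0.5, "fixed")
  expect_equal(q_param(fx, c(0.01, 0.5, 0.99)), rep(0.5, 3))

  set.seed(21)
  u <- runif(1e5)
  be <- fit_distribution("groups.non_ambulatory.p_hosp.y1", 0.347, 0.30, 0.40,
                         "beta")
  draws <- q_param(be, u)
  expect_lt(abs(mean(draws) - 0.347), 0.005)
  q <- quantile(draws, c(0.025, 0.975))
  expect_lt(abs(q[[1]] - 0.30), 0.30 * 0.02)
  expect_lt(abs(q[[2]] - 0.40), 0.40 * 0.02)

  ga <- fit_distribution("cost_inpatient_stay", 17985, 16000, 20000, "gamma")
  gd <- q_param(ga, u)
  expect_lt(abs(mean(gd) - 17985) / 17985, 0.01)
  gq <- quantile(gd, c(0.025, 0.975))
  expect_lt(abs(gq[[1]] - 16000) / 16000, 0.02)
  expect_lt(abs(gq[[2]] - 20000) / 20000, 0.02)

  expect_error(fit_distribution("x", 0.5, 0.6, 0.7, "beta"), "bracket")
  expect_error(fit_distribution("x", 1.2, 1.0, 1.5, "beta"), "probabilities")
})

test_that("one-way analysis is exact for degenerate and linear parameters", {
  inp <- model_inputs()
  base <- summarize_cohort(run_cohort(inp, "non_ambulatory"))$average_cost
  ow <- one_way(inp, "cost_inpatient_stay", 17985, 17985, "non_ambulatory")
  expect_equal(ow$pct_change_low, 0)
  expect_equal(ow$pct_change_high, 0)
  # the cost model is linear in the inpatient-stay cost: symmetric
  # multiplicative bounds give symmetric swings, and doubling the unit cost
  # adds exactly the base hospitalization component
  lin <- one_way(inp, "cost_inpatient_stay", 0, 2 * 17985, "non_ambulatory")
  expect_equal(lin$cost_at_low + lin$cost_at_high, 2 * base, tolerance = 1e-9)
  expect_equal(lin$pct_change_high, -lin$pct_change_low, tolerance = 1e-9)
  expect_error(one_way(inp, "groups.nowhere.p_uti.y1", 0.1, 0.2),
               "unknown parameter path")
})

test_that("hospitalization rate dominates the tornado under equal relative bounds", {
  inp <- model_inputs()
  dists <- default_psa_distributions(inp, rel_width = 0.15)
  tor <- tornado(inp, dists, "non_ambulatory")
  expect_true(grepl("p_hosp", tor$parameter[1]))
  hosp_sw <- max(tor$swing[grepl("p_hosp", tor$parameter)])
  other_sw <- max(tor$swing[!grepl("p_hosp", tor$parameter)])
  expect_gt(hosp_sw, other_sw)
  # base-case cost lies between the bound results (monotone parameters)
  expect_true(all(pmin(tor$cost_at_low, tor$cost_at_high) <= tor$base_cost + 1e-9 &
                    tor$base_cost <= pmax(tor$cost_at_low, tor$cost_at_high) + 1e-9))
})

test_that("PSA with all-fixed distributions collapses to the base case", {
  inp <- model_inputs()
  base_na <- summarize_cohort(run_cohort(inp, "non_ambulatory"))$average_cost
  base_am <- summarize_cohort(run_cohort(inp, "ambulatory"))$average_cost
  dists <- list(
    fit_distribution("cost_inpatient_stay", 17985, 17985, 17985, "fixed"),
    fit_distribution("groups.non_ambulatory.p_uti.y1", 0.733, 0.733, 0.733,
                     "fixed"))
  psa <- run_psa(inp, dists, n_iterations = 20, seed = 5)
  it <- psa$iterations
  expect_equal(unique(it$cost_non_ambulatory), base_na, tolerance = 1e-12)
  expect_equal(unique(it$cost_ambulatory), base_am, tolerance = 1e-12)
  s <- summarize_psa(psa)
  q <- s$quantiles[s$quantiles$statistic %in% c("Minimum", "Mean", "Maximum"), ]
  expect_equal(q$non_ambulatory, rep(base_na, 3), tolerance = 1e-12)
})

test_that("PSA is reproducible given the seed and consistent in the narrow limit", {
  inp <- model_inputs()
  dists <- default_psa_distributions(inp, rel_width = 0.1)
  a <- run_psa(inp, dists, n_iterations = 30, seed = 77)
  b <- run_psa(inp, dists, n_iterations = 30, seed = 77)
  expect_identical(a$iterations, b$iterations)
  c2 <- run_psa(inp, dists, n_iterations = 30, seed = 78)
  expect_false(identical(a$iterations, c2$iterations))
  # near-degenerate distributions reproduce the base case closely
  narrow <- default_psa_distributions(inp, rel_width = 1e-4,
                                      cost_ci = c(17984, 17986))
  base_na <- summarize_cohort(run_cohort(inp, "non_ambulatory"))$average_cost
  psa <- run_psa(inp, narrow, n_iterations = 50, seed = 9)
  expect_lt(max(abs(psa$iterations$cost_non_ambulatory - base_na)), 50)
})

test_that("PSA summaries bin and order correctly", {
  fake <- structure(list(iterations = data.frame(
    iter = 1:4, cost_non_ambulatory = rep(50000, 4),
    cost_ambulatory = rep(30000, 4),
    cost_difference = c(-25000, -25000, -25000, 5000)),
    n_iterations = 4L, seed = 1L, rejections = 0L), class = "psa_result")
  s <- summarize_psa(fake)
  h <- s$histogram
  expect_equal(sum(h$frequency), 4L)
  b1 <- h[h$bin == "-$30,000 to -$20,000", ]
  expect_equal(b1$frequency, 3L)
  expect_equal(b1$percentage, 75)
  expect_equal(b1$cumulative, 75)
  b2 <- h[h$bin == "$0 to $10,000", ]
  expect_equal(b2$frequency, 1L)
  expect_equal(b2$cumulative, 100)
  # histogram bins partition the line; cumulative is a running percentage sum
  expect_true(all(diff(h$cum_exact) >= 0))
  expect_equal(h$cum_exact[nrow(h)], 100)
  expect_equal(h$cum_exact, cumsum(h$pct_exact))
  expect_equal(h$bin_low[-1], h$bin_high[-nrow(h)])
  # single iteration: all quantiles collapse to the value
  one <- structure(list(iterations = data.frame(
    iter = 1L, cost_non_ambulatory = 47000, cost_ambulatory = 31000,
    cost_difference = -16000), n_iterations = 1L, seed = 1L,
    rejections = 0L), class = "psa_result")
  qs <- summarize_psa(one)$quantiles
  expect_equal(unique(qs$difference), -16000)
})

test_that("ambulatory costs are lower in the clear majority of PSA iterations", {
  inp <- model_inputs()
  dists <- default_psa_distributions(inp)
  psa <- run_psa(inp, dists, n_iterations = 200, seed = 12)
  expect_gt(mean(psa$iterations$cost_difference < 0), 0.65)
  expect_equal(psa$rejections, 0L)
})
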