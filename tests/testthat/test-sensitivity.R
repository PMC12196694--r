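psa_inputs <- function() {
  t1 <- tab1()
  list(baseline = t1$baseline, transitions = tab2(), costs = t1$costs,
       utilities = t1$utilities)
}

test_that("zero variation degenerates to the base case and seeds fix the draw", {
  inp <- psa_inputs()
  fit <- base_case()
  psa0 <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                  n_iterations = 25, variation = 0, seed = 1)
  expect_equal(psa0$samples$total_cost, rep(fit$total_cost, 25),
               tolerance = 1e-12)
  expect_equal(psa0$samples$total_qalys, rep(fit$total_qalys, 25),
               tolerance = 1e-12)

  a <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
               n_iterations = 200, seed = 42)
  b <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
               n_iterations = 200, seed = 42)
  expect_identical(a$samples, b$samples)
  c <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
               n_iterations = 200, seed = 43)
  expect_false(identical(a$samples$total_cost, c$samples$total_cost))
})

test_that("symmetric perturbation keeps the PSA centred on the base case", {
  inp <- psa_inputs()
  psa <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                 n_iterations = 2000, seed = 7)
  se_cost <- psa$summary["total_cost", "sd"] / sqrt(psa$n_iterations)
  se_q <- psa$summary["total_qalys", "sd"] / sqrt(psa$n_iterations)
  expect_lt(abs(psa$summary["total_cost", "mean"] - psa$base["total_cost"]),
            3 * se_cost + 0.001 * psa$base["total_cost"])
  expect_lt(abs(psa$summary["total_qalys", "mean"] - psa$base["total_qalys"]),
            3 * se_q + 0.001 * psa$base["total_qalys"])
  expect_equal(psa$fraction_below_wtp, 1)
  expect_equal(nrow(psa$samples), 2000)
  # every draw stays a valid model: positive costs, QALYs within the bound
  expect_true(all(psa$samples$total_cost > 0))
  expect_true(all(psa$samples$total_qalys <= 6 * 1.0))
})

test_that("explicit per-stage utility ranges are honoured", {
  inp <- psa_inputs()
  ranges <- cbind(low = rep(0.5, 4), high = rep(0.6, 4))
  psa <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                 n_iterations = 100, variation = 0, utility_variation = ranges,
                 seed = 3)
  # QALYs must fall inside the range-implied band (6 discounted evaluations)
  lo <- 0.5 * sum(1.05^-(0:5)); hi <- 0.6 * sum(1.05^-(0:5))
  expect_true(all(psa$samples$total_qalys >= lo & psa$samples$total_qalys <= hi))
  # costs untouched at zero structural variation
  expect_equal(stats::sd(psa$samples$total_cost), 0, tolerance = 1e-9)
})

test_that("a parameter scaling the whole cost schedule has impact equal to the variation", {
  inp <- psa_inputs()
  tor <- tornado(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                 parameters = "cost:ALL", variation = 0.07)
  expect_equal(tor$impact_pct, 7, tolerance = 1e-9)
  expect_equal(tor$low_total_cost, 0.93 * attr(tor, "base_cost"),
               tolerance = 1e-12)
})

test_that("tornado handles cover scalars, renormalized probabilities and items", {
  inp <- psa_inputs()
  items <- drug_residual_items(inp$costs, 94.40, drug_name = "BIC/FTC/TAF")
  tor <- tornado(inp$baseline, inp$transitions, utilities = inp$utilities,
                 items = items, variation = 0.07)
  # the drug price dominates and moves total cost by about 5%
  expect_equal(tor$parameter[1], "item:BIC/FTC/TAF")
  expect_equal(tor$impact_pct[1], 5, tolerance = 0.05)

  # baseline worst-stage share has a small positive impact (< 1%)
  tb <- tornado(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                parameters = "baseline:CD4_LT_200", variation = 0.07)
  expect_gt(tb$impact_pct, 0)
  expect_lt(tb$impact_pct, 1)

  # a parameter with zero base value moves nothing
  zero_costs <- cost_schedule(c(0, 100, 100, 100), rep(100, 4))
  tz <- tornado(inp$baseline, inp$transitions, zero_costs, inp$utilities,
                parameters = "initial_cost:CD4_LT_200", variation = 0.07)
  expect_equal(tz$impact_pct, 0)

  # utilities leave total cost untouched; transitions move it
  tu <- tornado(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                parameters = c("utility:CD4_GE_500",
                               "transition:1:CD4_LT_200:CD4_LT_200"))
  expect_equal(tu$impact_pct[tu$parameter == "utility:CD4_GE_500"], 0)
  expect_gt(tu$impact_pct[tu$parameter != "utility:CD4_GE_500"], 0)

  expect_error(tornado(inp$baseline, inp$transitions, inp$costs,
                       inp$utilities, parameters = "nonsense:handle"),
               "unknown parameter handle")
  expect_error(tornado(inp$baseline, inp$transitions, inp$costs,
                       inp$utilities, parameters = "item:BIC/FTC/TAF"),
               "resource-item table")
})

test_that("PSA and tornado outputs write as plot-ready delimited text", {
  inp <- psa_inputs()
  psa <- run_psa(inp$baseline, inp$transitions, inp$costs, inp$utilities,
                 n_iterations = 50, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_psa_samples(psa, f)
  back <- utils::read.csv(f)
  expect_named(back, c("iteration", "total_cost", "total_qalys", "cost_per_qaly"))
  expect_equal(nrow(back), 50)

  tor <- tornado(inp$baseline, inp$transitions, inp$costs, inp$utilities)
  g <- withr::local_tempfile(fileext = ".csv")
  write_tornado(tor, g)
  back_t <- utils::read.csv(g)
  expect_named(back_t, c("parameter", "low_total_cost", "high_total_cost",
                         "impact_pct"))
  # ranking is by impact, descending
  expect_true(all(diff(back_t$impact_pct) <= 0))
})
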