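test_that("advance reproduces hand-computed matrix-vector products", {
  trs <- tab2()
  y1 <- transition_matrix(trs, 1)

  # degenerate worst-stage cohort: result is the (renormalized) first row
  out <- advance(stage_vector(c(1, 0, 0, 0)), y1)
  expect_equal(unname(unclass(out)), c(0.38, 0.36, 0.20, 0.07) / 1.01,
               tolerance = 1e-12)

  # identity matrix leaves any state unchanged
  st <- stage_vector(c(0, 0, 0, 1))
  expect_equal(unclass(advance(st, diag(4))), unclass(st))

  # one cycle from the published baseline, best-stage share by hand:
  # sum over origins of baseline * renormalized P(origin -> >=500)
  base <- c(0.39, 0.22, 0.16, 0.23)
  expected_top <- base[1] * 0.07 / 1.01 + base[2] * 0.40 +
    base[3] * 0.61 + base[4] * 0.76
  out1 <- advance(stage_vector(base), y1)
  expect_equal(unname(out1[4]), expected_top, tolerance = 1e-12)
  expect_lt(abs(unname(out1[4]) - 0.388), 0.001)

  expect_error(advance(stage_vector(base), diag(3)), "4 x 4")
  expect_error(advance(stage_vector(base), -diag(4)), "negative")
})

test_that("an absorbing single-state cohort has the closed-form accruals", {
  t1 <- tab1()
  fit <- markov_cohort(stage_vector(c(0, 0, 0, 1)), identity_schedule(),
                       t1$costs, t1$utilities,
                       horizon = 5, discount_costs = 0, discount_qalys = 0)
  expect_equal(fit$total_qalys, 6 * 0.73, tolerance = 1e-12)
  expect_equal(fit$total_cost,
               unname(t1$costs$initial["CD4_GE_500"] +
                        5 * t1$costs$incremental["CD4_GE_500"]),
               tolerance = 1e-12)
  expect_true(all(fit$occupancy[, 4] == 1))
})

test_that("occupancy mass is conserved for arbitrary valid inputs", {
  set.seed(71)
  for (rep in 1:20) {
    fit <- markov_cohort(random_stage_vector(), random_schedule(3),
                         tab1()$costs, tab1()$utilities, horizon = 6)
    expect_equal(rowSums(fit$occupancy), rep(1, 7),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(fit$cost_accruals >= 0))
    expect_true(all(fit$qaly_accruals >= 0))
    # per-time QALY accrual is bounded by the best utility, discounted
    expect_true(all(fit$qaly_accruals <= 0.73 * 1.05^-(0:6) + 1e-12))
  }
})

test_that("totals are non-increasing in the discount rate and r=0 gives plain sums", {
  t1 <- tab1()
  rates <- c(0, 0.03, 0.05, 0.10)
  costs <- vapply(rates, function(r) {
    markov_cohort(t1$baseline, tab2(), t1$costs, t1$utilities,
                  discount_costs = r, discount_qalys = r)$total_cost
  }, numeric(1))
  qalys <- vapply(rates, function(r) {
    markov_cohort(t1$baseline, tab2(), t1$costs, t1$utilities,
                  discount_costs = r, discount_qalys = r)$total_qalys
  }, numeric(1))
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))

  # zero discount reproduces undiscounted stage-weighted sums from the trace
  fit0 <- markov_cohort(t1$baseline, tab2(), t1$costs, t1$utilities,
                        discount_costs = 0, discount_qalys = 0)
  manual_cost <- sum(fit0$occupancy[1, ] * t1$costs$initial) +
    sum(fit0$occupancy[-1, ] %*% t1$costs$incremental)
  manual_qalys <- sum(fit0$occupancy %*% unclass(t1$utilities))
  expect_equal(fit0$total_cost, manual_cost, tolerance = 1e-12)
  expect_equal(fit0$total_qalys, manual_qalys, tolerance = 1e-12)
})

test_that("total QALYs respect the horizon-times-best-utility bound", {
  fit <- base_case()
  expect_lte(fit$total_qalys, 6 * 0.73)
  set.seed(99)
  for (rep in 1:5) {
    f <- markov_cohort(random_stage_vector(), random_schedule(2),
                       tab1()$costs, tab1()$utilities, horizon = 5)
    expect_lte(f$total_qalys, 6 * 0.73)
  }
})

test_that("summary reports the ratio identity and degenerate cases", {
  fit <- base_case()
  s <- summary(fit)
  expect_equal(s$cost_per_qaly, s$total_cost / s$total_qalys, tolerance = 1e-12)
  expect_true(s$below_wtp)

  # a zero-cost schedule is trivially below any threshold
  zero <- markov_cohort(tab1()$baseline, tab2(),
                        cost_schedule(rep(0, 4), rep(0, 4)), tab1()$utilities)
  expect_equal(zero$total_cost, 0)
  expect_equal(summary(zero)$cost_per_qaly, 0)
  expect_true(zero$below_wtp)

  # all-zero utilities leave the ratio undefined
  dead <- markov_cohort(tab1()$baseline, tab2(), tab1()$costs,
                        utility_schedule(rep(0, 4)))
  expect_error(summary(dead), "undefined")
})

test_that("the trace exports and validates as a data frame", {
  fit <- base_case()
  d <- as.data.frame(fit)
  expect_equal(nrow(d), 6)
  expect_named(d, c("time", cd4_stages(), "discounted_cost", "discounted_qaly"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(fit, f)
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(back$discounted_cost, round(d$discounted_cost, 2))
})

test_that("microsimulation matches closed forms at n = 1 and varies by seed", {
  t1 <- tab1()
  fit <- markov_cohort(stage_vector(c(0, 0, 0, 1)), identity_schedule(),
                       t1$costs, t1$utilities)
  one <- simulate(fit, nsim = 1, seed = 5)
  # single absorbing path: microsim is exactly the deterministic accrual
  expect_equal(one$total_cost, fit$total_cost, tolerance = 1e-12)
  expect_equal(one$total_qalys, fit$total_qalys, tolerance = 1e-12)

  base <- base_case()
  a <- simulate(base, nsim = 20000, seed = 1)
  b <- simulate(base, nsim = 20000, seed = 2)
  expect_false(identical(a$total_cost, b$total_cost))
  expect_lt(abs(a$total_cost - b$total_cost) / base$total_cost, 0.005)
  # same seed is bit-identical
  expect_identical(simulate(base, nsim = 5000, seed = 3)$total_cost,
                   simulate(base, nsim = 5000, seed = 3)$total_cost)
})
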