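test_that("transitions are counted from consecutive observed pairs only", {
  # one improving patient: <200 -> 200-349 -> 350-499
  panel <- panel_from_cd4(list(c(150, 250, 400)))
  counts <- count_transitions(panel, max_year = 2)
  expect_equal(counts[[1]]["CD4_LT_200", "CD4_200_349"], 1L)
  expect_equal(sum(counts[[1]]), 1L)
  expect_equal(counts[[2]]["CD4_200_349", "CD4_350_499"], 1L)
  expect_equal(sum(counts[[2]]), 1L)

  # a gap in follow-up produces no counts
  gappy <- data.frame(patient_id = "P1", year_index = c(0, 2),
                      cd4_count = c(150, 400))
  counts_g <- count_transitions(gappy, max_year = 2)
  expect_equal(sum(counts_g[[1]]) + sum(counts_g[[2]]), 0L)

  # pairs beyond max_year are ignored
  counts_1 <- count_transitions(panel, max_year = 1)
  expect_length(counts_1, 1)
  expect_error(count_transitions(panel, max_year = 0), "at least 1")
})

test_that("baseline estimation classifies year-0 CD4 counts", {
  panel <- panel_from_cd4(list(100, 250, 400, 600))
  expect_equal(unname(unclass(estimate_baseline(panel))), rep(0.25, 4))
  # ART-experienced patients are excluded when flagged
  panel$art_naive <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(unname(unclass(estimate_baseline(panel))),
               c(1, 1, 1, 0) / 3)
  expect_error(estimate_baseline(panel_from_cd4(list(c(100, 200)), start_year = 1)),
               "year-0")
  expect_error(estimate_baseline(data.frame(patient_id = character(),
                                            year_index = integer(),
                                            cd4_count = numeric())), "empty")
})

test_that("row proportions, smoothing and zero-row fallback behave as documented", {
  cm <- matrix(0L, 4, 4, dimnames = list(cd4_stages(), cd4_stages()))
  cm[1, ] <- c(38L, 36L, 20L, 7L)
  cm[2, ] <- c(1L, 10L, 10L, 9L)
  cm[3, ] <- c(0L, 2L, 10L, 18L)
  cm[4, ] <- c(0L, 1L, 6L, 23L)
  counts <- structure(list(cm), class = "transition_counts")
  sched <- estimate_transitions(counts, carry_forward_from = 1)
  expect_equal(unname(sched$matrices[[1]][1, ]), c(38, 36, 20, 7) / 101,
               tolerance = 1e-12)
  expect_equal(rowSums(sched$matrices[[1]]), rep(1, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero row: Laplace smoothing gives the uniform row...
  cm0 <- cm
  cm0[2, ] <- 0L
  counts0 <- structure(list(cm0), class = "transition_counts")
  smoothed <- estimate_transitions(counts0, carry_forward_from = 1, smoothing = 1)
  expect_equal(unname(smoothed$matrices[[1]][2, ]), rep(0.25, 4))
  # ...and no smoothing falls back to the identity row with a warning
  expect_warning(ident <- estimate_transitions(counts0, carry_forward_from = 1),
                 "identity row")
  expect_equal(unname(ident$matrices[[1]][2, ]), c(0, 1, 0, 0))

  expect_error(estimate_transitions(counts, carry_forward_from = 0), "at least 1")
  expect_error(estimate_transitions(counts, carry_forward_from = 2), "cover")
})

test_that("the fitted schedule carries year 3 forward to model years 4 and 5", {
  panel <- simulate_panel(n_patients = 400, years = 5, seed = 8)
  fit <- fit_transitions(panel, max_year = 3)
  expect_identical(transition_matrix(fit$schedule, 5),
                   transition_matrix(fit$schedule, 3))
  expect_equal(fit$n_patients, 400)
})

test_that("counts conserve the number of consecutive pairs", {
  panel <- simulate_panel(n_patients = 300, years = 4, seed = 12,
                          dropout_rate = 0.15)
  panel <- degrade_panel(panel, missing_rate = 0.2, seed = 13)
  counts <- count_transitions(panel, max_year = 4)
  # independent tally of consecutive pairs per destination year
  panel <- panel[order(panel$patient_id, panel$year_index), ]
  pairs <- table(factor(
    panel$year_index[-1][panel$patient_id[-1] == panel$patient_id[-nrow(panel)] &
                           diff(panel$year_index) == 1],
    levels = 1:4))
  expect_equal(vapply(unclass(counts), sum, numeric(1)),
               as.numeric(pairs), ignore_attr = TRUE)
})

test_that("estimates recover the generating matrices, improving with n", {
  truth <- tab2()$matrices
  fit_at <- function(n, seed) {
    panel <- simulate_panel(n_patients = n, years = 3, seed = seed)
    fit_transitions(panel, max_year = 3)
  }
  err_of <- function(fit) {
    max(vapply(1:3, function(y) max(abs(coef(fit)[[y]] - truth[[y]])),
               numeric(1)))
  }
  small <- fit_at(500, 21)
  mid <- fit_at(5000, 22)
  expect_lt(err_of(mid), err_of(small))

  # every estimated cell sits within 3 binomial standard errors of the truth
  # (sparsely visited origin rows have legitimately larger errors)
  for (y in 1:3) {
    row_n <- rowSums(unclass(mid$counts)[[y]])
    se <- sqrt(truth[[y]] * (1 - truth[[y]]) / row_n)
    expect_true(all(abs(coef(mid)[[y]] - truth[[y]]) <= 3 * se + 1e-12))
  }

  # baseline recovery at large n
  big <- simulate_panel(n_patients = 10000, years = 0, seed = 23)
  est <- estimate_baseline(big)
  expect_lt(max(abs(unclass(est) - unclass(tab1()$baseline))), 0.02)
})

test_that("panels round-trip through delimited text", {
  panel <- simulate_panel(n_patients = 25, years = 2, seed = 31)
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, f)
  back <- read_panel(f)
  expect_equal(back$cd4_count, panel$cd4_count, tolerance = 1e-9)
  expect_identical(back$patient_id, panel$patient_id)
  dup <- rbind(panel, panel[1, ])
  expect_error(write_panel(dup, f), "duplicated")
})
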