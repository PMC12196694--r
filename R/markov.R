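#' Advance a stage-occupancy vector by one annual cycle
#'
#' Left-multiplies the occupancy vector by a row-stochastic transition matrix
#' (rows = origin stage, columns = destination stage).
#'
#' @param state A [stage_vector()] or a 4-vector coercible to one.
#' @param matrix A 4 x 4 matrix with non-negative entries; rows are
#'   renormalized if they stray from sum 1.
#' @return A [stage_vector()] for the next model time.
#' @export
advance <- function(state, matrix) {
  if (!inherits(state, "stage_vector")) state <- stage_vector(state)
  if (!is.matrix(matrix) || !all(dim(matrix) == c(4L, 4L))) {
    stop("'matrix' must be 4 x 4", call. = FALSE)
  }
  if (any(matrix < 0)) stop("transition matrix has negative entries", call. = FALSE)
  matrix <- sweep(matrix, 1, rowSums(matrix), "/")
  stage_vector(as.numeric(unclass(state) %*% matrix))
}

#' Run the CD4-stage Markov cohort cost-utility model
#'
#' Evolves a cohort's distribution over the four CD4 stages through annual
#' cycles and accrues discounted costs and QALYs. Costs and utilities are
#' evaluated at model times t = 0..horizon — the baseline state plus one
#' state per completed cycle, horizon + 1 evaluation points in all — with no
#' half-cycle correction. The stage-weighted initial cost is accrued at
#' t = 0 (undiscounted); stage-weighted incremental costs at t = 1..horizon
#' and stage-weighted utilities at t = 0..horizon are discounted by
#' (1 + r)^-t. The model has no death state: occupancy mass is conserved,
#' though absorbing rows (a unit row) are handled without special-casing.
#'
#' @param baseline [stage_vector()] of starting stage probabilities.
#' @param transitions [transition_schedule()]; cycles past its last estimated
#'   year reuse that year's matrix.
#' @param costs [cost_schedule()] of per-stage initial/incremental USD costs.
#' @param utilities [utility_schedule()] of per-stage QALY weights.
#' @param horizon Number of annual cycles (default 5).
#' @param discount_costs,discount_qalys Annual discount rates in \[0, 1)
#'   (default 0.05 each).
#' @param wtp Willingness-to-pay threshold in USD per QALY (default 13790,
#'   one GDP per capita under Mexican economic-evaluation guidance).
#' @return Object of class `markov_cohort`: a list with `occupancy`
#'   ((horizon + 1) x 4 trace matrix, rows indexed by model time 0..horizon),
#'   `cost_accruals` and `qaly_accruals` (discounted per-time accruals),
#'   `total_cost`, `total_qalys`, `cost_per_qaly`, `below_wtp`, the inputs,
#'   and the call.
#' @examples
#' inp <- load_fixtures("table1")
#' trs <- load_fixtures("table2")
#' fit <- markov_cohort(inp$baseline, trs, inp$costs, inp$utilities)
#' summary(fit)
#' @export
markov_cohort <- function(baseline, transitions, costs, utilities,
                          horizon = 5, discount_costs = 0.05,
                          discount_qalys = 0.05, wtp = 13790) {
  if (!inherits(baseline, "stage_vector")) baseline <- stage_vector(baseline)
  stopifnot(inherits(transitions, "transition_schedule"),
            inherits(costs, "cost_schedule"),
            inherits(utilities, "utility_schedule"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("'horizon' must be at least 1", call. = FALSE)
  for (r in c(discount_costs, discount_qalys)) {
    if (r < 0 || r >= 1) stop("discount rates must lie in [0, 1)", call. = FALSE)
  }
  if (wtp <= 0) stop("'wtp' must be positive", call. = FALSE)

  occ <- matrix(0, horizon + 1L, 4L,
                dimnames = list(time = 0:horizon, stage = cd4_stages()))
  occ[1L, ] <- unclass(baseline)
  for (t in seq_len(horizon)) {
    occ[t + 1L, ] <- unclass(advance(occ[t, ], transition_matrix(transitions, t)))
  }

  disc_c <- (1 + discount_costs)^-(0:horizon)
  disc_q <- (1 + discount_qalys)^-(0:horizon)
  # initial costs at t = 0, incremental at t >= 1
  raw_cost <- c(sum(occ[1L, ] * costs$initial),
                as.numeric(occ[-1L, , drop = FALSE] %*% costs$incremental))
  cost_accruals <- raw_cost * disc_c
  qaly_accruals <- as.numeric(occ %*% unclass(utilities)) * disc_q

  total_cost <- sum(cost_accruals)
  total_qalys <- sum(qaly_accruals)
  cost_per_qaly <- if (total_qalys > 0) total_cost / total_qalys else NA_real_

  structure(list(
    occupancy = occ,
    cost_accruals = cost_accruals,
    qaly_accruals = qaly_accruals,
    total_cost = total_cost,
    total_qalys = total_qalys,
    cost_per_qaly = cost_per_qaly,
    below_wtp = isTRUE(cost_per_qaly <= wtp),
    horizon = horizon,
    discount_costs = discount_costs,
    discount_qalys = discount_qalys,
    wtp = wtp,
    inputs = list(baseline = baseline, transitions = transitions,
                  costs = costs, utilities = utilities),
    call = match.call()
  ), class = "markov_cohort")
}

#' @export
print.markov_cohort <- function(x, ...) {
  cat("CD4-stage Markov cohort cost-utility model\n")
  cat(sprintf("  horizon: %d annual cycles; discounting %.1f%% (costs), %.1f%% (QALYs)\n",
              x$horizon, 100 * x$discount_costs, 100 * x$discount_qalys))
  cat(sprintf("  cumulative cost:  USD %.2f per person\n", x$total_cost))
  cat(sprintf("  cumulative QALYs: %.4f per person\n", x$total_qalys))
  if (is.na(x$cost_per_qaly)) {
    cat("  cost per QALY: undefined (zero QALYs)\n")
  } else {
    cat(sprintf("  cost per QALY: USD %.2f (%s WTP of USD %.0f)\n",
                x$cost_per_qaly, if (x$below_wtp) "below" else "above", x$wtp))
  }
  invisible(x)
}

#' Summarize a Markov cohort run as a cost-utility result
#'
#' Collapses the trace to the headline cost-utility quantities: cumulative
#' discounted cost and QALYs per person, their ratio, and the verdict
#' against the willingness-to-pay threshold.
#'
#' @param object A [markov_cohort()] fit.
#' @param ... Unused.
#' @return Object of class `summary.markov_cohort`: list with `total_cost`,
#'   `total_qalys`, `cost_per_qaly`, `below_wtp`, `wtp`, `horizon`.
#' @export
summary.markov_cohort <- function(object, ...) {
  if (object$total_qalys <= 0) {
    stop("cost per QALY is undefined: total QALYs are zero", call. = FALSE)
  }
  structure(list(total_cost = object$total_cost,
                 total_qalys = object$total_qalys,
                 cost_per_qaly = object$total_cost / object$total_qalys,
                 below_wtp = object$below_wtp,
                 wtp = object$wtp,
                 horizon = object$horizon),
            class = "summary.markov_cohort")
}

#' @export
print.summary.markov_cohort <- function(x, ...) {
  cat(sprintf("%d-year cost-utility summary (per person, discounted)\n", x$horizon))
  cat(sprintf("  total cost:    USD %.2f\n", x$total_cost))
  cat(sprintf("  total QALYs:   %.4f\n", x$total_qalys))
  cat(sprintf("  cost per QALY: USD %.2f\n", x$cost_per_qaly))
  cat(sprintf("  %s the willingness-to-pay threshold of USD %.0f/QALY\n",
              if (x$below_wtp) "below" else "ABOVE", x$wtp))
  invisible(x)
}

#' @export
as.data.frame.markov_cohort <- function(x, ...) {
  data.frame(time = 0:x$horizon,
             x$occupancy,
             discounted_cost = x$cost_accruals,
             discounted_qaly = x$qaly_accruals,
             row.names = NULL, check.names = FALSE)
}

#' Write a cohort trace as delimited text
#'
#' Columns: `time`, the four stage occupancies, `discounted_cost`,
#' `discounted_qaly` (monetary values to 2 decimals, probabilities to 4).
#'
#' @param x A [markov_cohort()] fit.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_trace <- function(x, file) {
  stopifnot(inherits(x, "markov_cohort"))
  d <- as.data.frame(x)
  d[cd4_stages()] <- round(d[cd4_stages()], 4)
  d$discounted_cost <- round(d$discounted_cost, 2)
  d$discounted_qaly <- round(d$discounted_qaly, 4)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

#' Plot the cohort trace
#'
#' Stage occupancy over model time, one line per CD4 stage.
#'
#' @param x A [markov_cohort()] fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.markov_cohort <- function(x, ...) {
  graphics::matplot(0:x$horizon, x$occupancy, type = "b", pch = 19, lty = 1,
                    xlab = "Model year", ylab = "Stage occupancy",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = cd4_stages(), col = 1:4, lty = 1,
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Individual-level microsimulation of the cohort model
#'
#' Brute-force cross-check of the deterministic cohort trace: samples
#' `nsim` individual stage paths by categorical draws from the same baseline
#' and transition matrices, accrues each individual's discounted costs and
#' QALYs under the identical convention, and averages. The means converge to
#' the [markov_cohort()] totals as `nsim` grows.
#'
#' @param object A [markov_cohort()] fit (supplies inputs and settings).
#' @param nsim Number of simulated individuals.
#' @param seed Optional integer seed for reproducibility.
#' @param ... Unused.
#' @return Object of class `markov_microsim`: list with `total_cost` and
#'   `total_qalys` (means over individuals), their standard errors `se_cost`
#'   and `se_qalys`, `cost_per_qaly` (ratio of means), and `nsim`.
#' @export
simulate.markov_cohort <- function(object, nsim = 10000, seed = NULL, ...) {
  nsim <- as.integer(nsim)
  if (nsim < 1L) stop("'nsim' must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  horizon <- object$horizon
  base <- unclass(object$inputs$baseline)
  costs <- object$inputs$costs
  u <- unclass(object$inputs$utilities)
  disc_c <- (1 + object$discount_costs)^-(0:horizon)
  disc_q <- (1 + object$discount_qalys)^-(0:horizon)

  state <- sample.int(4L, nsim, replace = TRUE, prob = base)
  cost_i <- costs$initial[state] * disc_c[1L]
  qaly_i <- u[state] * disc_q[1L]
  for (t in seq_len(horizon)) {
    m <- transition_matrix(object$inputs$transitions, t)
    nxt <- integer(nsim)
    for (s in 1:4) {
      idx <- which(state == s)
      if (length(idx)) {
        nxt[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = m[s, ])
      }
    }
    state <- nxt
    cost_i <- cost_i + costs$incremental[state] * disc_c[t + 1L]
    qaly_i <- qaly_i + u[state] * disc_q[t + 1L]
  }

  structure(list(total_cost = mean(cost_i),
                 total_qalys = mean(qaly_i),
                 se_cost = stats::sd(cost_i) / sqrt(nsim),
                 se_qalys = stats::sd(qaly_i) / sqrt(nsim),
                 cost_per_qaly = mean(cost_i) / mean(qaly_i),
                 nsim = nsim),
            class = "markov_microsim")
}

#' @export
print.markov_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation of %d individuals\n", x$nsim))
  cat(sprintf("  mean cost:  USD %.2f (se %.2f)\n", x$total_cost, x$se_cost))
  cat(sprintf("  mean QALYs: %.4f (se %.4f)\n", x$total_qalys, x$se_qalys))
  cat(sprintf("  cost per QALY: USD %.2f\n", x$cost_per_qaly))
  invisible(x)
}
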