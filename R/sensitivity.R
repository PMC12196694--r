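# Fast inner loop shared by the PSA and tornado: plain arithmetic on
# pre-resolved inputs, no class validation. `mats` is a list of length
# `horizon` (carry-forward already applied); rows must be normalized by the
# caller. Returns c(cost, qalys).
.run_cua <- function(base, mats, init, incr, u, horizon, rc, rq) {
  occ <- base
  disc_c <- (1 + rc)^-(0:horizon)
  disc_q <- (1 + rq)^-(0:horizon)
  cost <- sum(occ * init)
  qaly <- sum(occ * u)
  for (t in seq_len(horizon)) {
    occ <- as.numeric(occ %*% mats[[t]])
    cost <- cost + sum(occ * incr) * disc_c[t + 1L]
    qaly <- qaly + sum(occ * u) * disc_q[t + 1L]
  }
  c(cost, qaly)
}

.resolve_mats <- function(transitions, horizon) {
  lapply(seq_len(horizon), function(t) transition_matrix(transitions, t))
}

.renorm_rows <- function(m) sweep(m, 1, rowSums(m), "/")

#' Probabilistic sensitivity analysis of the cohort model
#'
#' Monte Carlo re-evaluation under joint perturbation of all model inputs:
#' every unit cost, utility, baseline probability and transition probability
#' is multiplied by an independent draw from Uniform(1 - v, 1 + v).
#' Utilities are clamped to \[0, 1\]; the baseline vector and every matrix
#' row are renormalized after perturbation so each draw remains a valid
#' probability structure. With a fixed seed the result is bit-reproducible.
#'
#' @param baseline,transitions,costs,utilities Base-case model inputs as in
#'   [markov_cohort()].
#' @param n_iterations Number of Monte Carlo draws (default 10000).
#' @param variation Half-width `v` of the multiplicative uniform band
#'   (default 0.07).
#' @param utility_variation Either a single half-width for utilities
#'   (default `variation`) or a 4 x 2 matrix of explicit per-stage
#'   (low, high) utility ranges sampled uniformly.
#' @param seed Optional integer seed.
#' @param horizon,discount_costs,discount_qalys,wtp As in [markov_cohort()].
#' @return Object of class `psa_result`: `samples` (data frame with
#'   `iteration`, `total_cost`, `total_qalys`, `cost_per_qaly`), `summary`
#'   (mean, sd, 2.5/97.5 percentiles per outcome), `fraction_below_wtp`,
#'   `base` (base-case cost/QALYs), and the settings.
#' @examples
#' inp <- load_fixtures("table1")
#' psa <- run_psa(inp$baseline, load_fixtures("table2"), inp$costs,
#'                inp$utilities, n_iterations = 200, seed = 1)
#' psa$fraction_below_wtp
#' @export
run_psa <- function(baseline, transitions, costs, utilities,
                    n_iterations = 10000, variation = 0.07,
                    utility_variation = variation, seed = NULL,
                    horizon = 5, discount_costs = 0.05,
                    discount_qalys = 0.05, wtp = 13790) {
  if (!inherits(baseline, "stage_vector")) baseline <- stage_vector(baseline)
  stopifnot(inherits(transitions, "transition_schedule"),
            inherits(costs, "cost_schedule"),
            inherits(utilities, "utility_schedule"))
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("'n_iterations' must be at least 1", call. = FALSE)
  if (variation < 0 || variation >= 1) {
    stop("'variation' must lie in [0, 1)", call. = FALSE)
  }
  u_ranges <- NULL
  if (is.matrix(utility_variation)) {
    if (!all(dim(utility_variation) == c(4L, 2L))) {
      stop("'utility_variation' matrix must be 4 x 2 (low, high)", call. = FALSE)
    }
    u_ranges <- utility_variation
  } else if (utility_variation < 0 || utility_variation >= 1) {
    stop("'utility_variation' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  base <- unclass(baseline)
  u <- unclass(utilities)
  init <- unname(costs$initial)
  incr <- unname(costs$incremental)
  n_years <- transitions$last_estimated_year
  est_mats <- transitions$matrices[seq_len(n_years)]
  year_of_cycle <- pmin(seq_len(horizon), n_years)

  cost_s <- qaly_s <- numeric(n_iterations)
  for (i in seq_len(n_iterations)) {
    mult <- function(x) x * stats::runif(length(x), 1 - variation, 1 + variation)
    b <- mult(base); b <- b / sum(b)
    if (is.null(u_ranges)) {
      ui <- u * stats::runif(4, 1 - utility_variation, 1 + utility_variation)
    } else {
      ui <- stats::runif(4, u_ranges[, 1], u_ranges[, 2])
    }
    ui <- pmin(1, pmax(0, ui))
    pm <- lapply(est_mats, function(m) .renorm_rows(matrix(mult(m), 4L, 4L)))
    res <- .run_cua(b, pm[year_of_cycle], mult(init), mult(incr), ui,
                    horizon, discount_costs, discount_qalys)
    cost_s[i] <- res[1L]
    qaly_s[i] <- res[2L]
  }

  samples <- data.frame(iteration = seq_len(n_iterations),
                        total_cost = cost_s, total_qalys = qaly_s,
                        cost_per_qaly = cost_s / qaly_s)
  stat <- function(x) c(mean = mean(x), sd = stats::sd(x),
                        stats::quantile(x, c(0.025, 0.975)))
  base_run <- .run_cua(base, .resolve_mats(transitions, horizon), init, incr,
                       u, horizon, discount_costs, discount_qalys)
  structure(list(
    samples = samples,
    summary = rbind(total_cost = stat(cost_s), total_qalys = stat(qaly_s),
                    cost_per_qaly = stat(samples$cost_per_qaly)),
    fraction_below_wtp = mean(samples$cost_per_qaly <= wtp),
    base = c(total_cost = base_run[1L], total_qalys = base_run[2L]),
    n_iterations = n_iterations, variation = variation, wtp = wtp
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations, +/-%.0f%% uniform variation\n",
              x$n_iterations, 100 * x$variation))
  print(round(x$summary, 4))
  cat(sprintf("fraction of iterations below WTP (USD %.0f/QALY): %.4f\n",
              x$wtp, x$fraction_below_wtp))
  invisible(x)
}

#' Plot a PSA result on the cost-effectiveness plane
#'
#' Scatter of per-iteration total QALYs against total cost, with the
#' base case marked.
#'
#' @param x A [run_psa()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psa_result <- function(x, ...) {
  graphics::plot(x$samples$total_qalys, x$samples$total_cost,
                 pch = 16, cex = 0.4, col = grDevices::grey(0.4, 0.5),
                 xlab = "Total QALYs per person",
                 ylab = "Total cost per person (USD)", ...)
  graphics::points(x$base["total_qalys"], x$base["total_cost"],
                   pch = 4, col = "red", lwd = 2)
  invisible(x)
}

#' Write PSA samples as delimited text
#'
#' @param x A [run_psa()] result.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_psa_samples <- function(x, file) {
  stopifnot(inherits(x, "psa_result"))
  d <- x$samples
  d$total_cost <- round(d$total_cost, 2)
  d$total_qalys <- round(d$total_qalys, 4)
  d$cost_per_qaly <- round(d$cost_per_qaly, 2)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}

# Apply one parameter handle at multiplier k; returns list(base, mats, init,
# incr, u) ready for .run_cua. Handles:
#   cost:ALL, initial_cost:<stage>, incremental_cost:<stage>,
#   utility:<stage>, baseline:<stage>, transition:<year>:<from>:<to>,
#   item:<name> (requires a resource-item table)
.apply_handle <- function(handle, k, base, est_mats, init, incr, u, items,
                          mxn_per_usd) {
  parts <- strsplit(handle, ":", fixed = TRUE)[[1]]
  kind <- parts[1L]
  stage_idx <- function(lab) {
    i <- match(lab, cd4_stages())
    if (is.na(i)) stop("unknown stage in handle: ", handle, call. = FALSE)
    i
  }
  if (kind == "cost" && identical(parts[2L], "ALL")) {
    init <- init * k; incr <- incr * k
  } else if (kind == "initial_cost") {
    i <- stage_idx(parts[2L]); init[i] <- init[i] * k
  } else if (kind == "incremental_cost") {
    i <- stage_idx(parts[2L]); incr[i] <- incr[i] * k
  } else if (kind == "utility") {
    i <- stage_idx(parts[2L]); u[i] <- min(1, max(0, u[i] * k))
  } else if (kind == "baseline") {
    i <- stage_idx(parts[2L]); base[i] <- base[i] * k; base <- base / sum(base)
  } else if (kind == "transition") {
    y <- as.integer(parts[2L])
    if (is.na(y) || y < 1L || y > length(est_mats)) {
      stop("unknown year in handle: ", handle, call. = FALSE)
    }
    i <- stage_idx(parts[3L]); j <- stage_idx(parts[4L])
    m <- est_mats[[y]]
    m[i, j] <- m[i, j] * k
    est_mats[[y]] <- .renorm_rows(m)
  } else if (kind == "item") {
    if (is.null(items)) {
      stop("handle '", handle, "' needs a resource-item table", call. = FALSE)
    }
    nm <- paste(parts[-1L], collapse = ":")
    hit <- items$name == nm
    if (!any(hit)) stop("no resource item named '", nm, "'", call. = FALSE)
    items$unit_cost[hit] <- items$unit_cost[hit] * k
    sched <- build_cost_schedule(items = items, mxn_per_usd = mxn_per_usd)
    init <- unname(sched$initial); incr <- unname(sched$incremental)
  } else {
    stop("unknown parameter handle: ", handle, call. = FALSE)
  }
  list(base = base, mats = est_mats, init = init, incr = incr, u = u)
}

#' One-way (tornado) sensitivity analysis of total cost
#'
#' Re-runs the cohort model with each named parameter alone at
#' `(1 - v)` and `(1 + v)` times its base value — renormalizing any
#' perturbed probability structure — and ranks parameters by their largest
#' percent deviation of total discounted cost from the base case.
#'
#' Parameter handles are strings: `"cost:ALL"` (every stage-year cost),
#' `"initial_cost:<stage>"`, `"incremental_cost:<stage>"`,
#' `"utility:<stage>"`, `"baseline:<stage>"`,
#' `"transition:<year>:<from>:<to>"`, or `"item:<name>"` to vary one
#' resource line item's unit cost (requires `items`, from which the cost
#' schedule is then rebuilt per run).
#'
#' @param baseline,transitions,utilities Base-case inputs as in
#'   [markov_cohort()].
#' @param costs Base-case [cost_schedule()]; ignored (rebuilt) when `items`
#'   is given.
#' @param parameters Character vector of handles. Defaults to every item
#'   name when `items` is supplied, otherwise the whole-schedule cost handle
#'   plus each baseline and utility entry.
#' @param variation One-way half-width `v` (default 0.07).
#' @param items Optional [resource_items()] table backing `item:` handles.
#' @param horizon,discount_costs,discount_qalys As in [markov_cohort()].
#' @param mxn_per_usd Exchange rate used when rebuilding costs from items.
#' @return Object of class `tornado_result`: data frame with `parameter`,
#'   `low_total_cost`, `high_total_cost`, `impact_pct`, ranked by
#'   `impact_pct` descending, with the base-case cost as attribute
#'   `base_cost`.
#' @export
tornado <- function(baseline, transitions, costs = NULL, utilities,
                    parameters = NULL, variation = 0.07, items = NULL,
                    horizon = 5, discount_costs = 0.05, discount_qalys = 0.05,
                    mxn_per_usd = 18.22) {
  if (!inherits(baseline, "stage_vector")) baseline <- stage_vector(baseline)
  stopifnot(inherits(transitions, "transition_schedule"),
            inherits(utilities, "utility_schedule"))
  if (variation < 0 || variation >= 1) {
    stop("'variation' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(items)) {
    items <- resource_items(items)
    costs <- build_cost_schedule(items = items, mxn_per_usd = mxn_per_usd)
  }
  stopifnot(inherits(costs, "cost_schedule"))
  if (is.null(parameters)) {
    parameters <- if (!is.null(items)) {
      paste0("item:", unique(items$name))
    } else {
      c("cost:ALL", paste0("utility:", cd4_stages()),
        paste0("baseline:", cd4_stages()))
    }
  }

  base <- unclass(baseline)
  u <- unclass(utilities)
  init <- unname(costs$initial)
  incr <- unname(costs$incremental)
  n_years <- transitions$last_estimated_year
  est_mats <- transitions$matrices[seq_len(n_years)]
  year_of_cycle <- pmin(seq_len(horizon), n_years)

  run_with <- function(handle, k) {
    p <- .apply_handle(handle, k, base, est_mats, init, incr, u, items,
                       mxn_per_usd)
    .run_cua(p$base, p$mats[year_of_cycle], p$init, p$incr, p$u, horizon,
             discount_costs, discount_qalys)[1L]
  }
  base_cost <- .run_cua(base, est_mats[year_of_cycle], init, incr, u, horizon,
                        discount_costs, discount_qalys)[1L]

  lo <- vapply(parameters, run_with, numeric(1), k = 1 - variation)
  hi <- vapply(parameters, run_with, numeric(1), k = 1 + variation)
  impact <- pmax(abs(lo - base_cost), abs(hi - base_cost)) / base_cost * 100

  out <- data.frame(parameter = parameters, low_total_cost = unname(lo),
                    high_total_cost = unname(hi), impact_pct = unname(impact),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$impact_pct), ]
  rownames(out) <- NULL
  structure(out, base_cost = base_cost,
            class = c("tornado_result", "data.frame"))
}

#' @export
print.tornado_result <- function(x, digits = 2, ...) {
  cat(sprintf("One-way sensitivity of total cost (base case USD %.2f)\n",
              attr(x, "base_cost")))
  d <- as.data.frame(x)
  d$low_total_cost <- round(d$low_total_cost, digits)
  d$high_total_cost <- round(d$high_total_cost, digits)
  d$impact_pct <- round(d$impact_pct, digits)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Plot a tornado diagram
#'
#' Horizontal bars spanning each parameter's low/high total cost, widest
#' impact on top.
#'
#' @param x A [tornado()] result.
#' @param n_top Number of parameters to show (default all).
#' @param ... Passed to [graphics::barplot()] machinery (unused).
#' @export
plot.tornado_result <- function(x, n_top = nrow(x), ...) {
  d <- as.data.frame(x)[seq_len(min(n_top, nrow(x))), ]
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_cost")
  op <- graphics::par(mar = c(5, 12, 2, 2))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(c(d$low_total_cost, d$high_total_cost, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "Total cost per person (USD)", ylab = "")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::segments(d$low_total_cost, seq_len(nrow(d)), d$high_total_cost,
                     seq_len(nrow(d)), lwd = 8, col = "steelblue", lend = 1)
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

#' Write a tornado result as delimited text
#'
#' @param x A [tornado()] result.
#' @param file Output CSV path.
#' @return Invisibly, `file`.
#' @export
write_tornado <- function(x, file) {
  stopifnot(inherits(x, "tornado_result"))
  d <- as.data.frame(x)
  d[-1] <- lapply(d[-1], round, 4)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
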