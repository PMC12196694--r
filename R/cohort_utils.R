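#' Sample size for estimating a single proportion
#'
#' Classic descriptive-study formula `ceil(z^2 p (1 - p) / margin^2)` with
#' `z` the two-sided standard-normal quantile for the confidence level.
#'
#' @param p Anticipated proportion, in (0, 1); `p` of exactly 0 or 1 returns
#'   0 with a warning.
#' @param confidence Confidence level (default 0.95).
#' @param margin Absolute margin of error (default 0.05).
#' @return Required sample size (integer, rounded up).
#' @examples
#' sample_size_proportion(0.79)  # 255
#' @export
sample_size_proportion <- function(p, confidence = 0.95, margin = 0.05) {
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]", call. = FALSE)
  if (confidence <= 0 || confidence >= 1 || margin <= 0 || margin >= 1) {
    stop("'confidence' and 'margin' must lie in (0, 1)", call. = FALSE)
  }
  if (p == 0 || p == 1) {
    warning("degenerate proportion; sample size is 0", call. = FALSE)
    return(0L)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  as.integer(ceiling(z^2 * p * (1 - p) / margin^2))
}

#' Project clinic-level budget under population growth
#'
#' Scales the per-person annual cost of care to a served population growing
#' geometrically: `series[t] = per_person_annual_cost * population *
#' (1 + growth_rate)^t` for `t = 0..horizon`. The per-person annual cost is
#' the model's cumulative cost divided by its horizon in years.
#'
#' @param result A [markov_cohort()] fit or its [summary()]; alternatively a
#'   single numeric per-person annual cost in USD.
#' @param population Number of people in care at year 0.
#' @param growth_rate Annual growth of the served population as a fraction
#'   (default 0.121).
#' @param horizon Projection years beyond year 0 (default 5).
#' @return Object of class `budget_projection`: list with
#'   `per_person_annual_cost`, `population`, `growth_rate`, and `series`
#'   (named USD totals for years 0..horizon).
#' @examples
#' bp <- project_budget(8431.95 / 5, population = 21749)
#' bp$series[1]  # ~36.7 million USD
#' @export
project_budget <- function(result, population, growth_rate = 0.121,
                           horizon = 5) {
  if (inherits(result, c("markov_cohort", "summary.markov_cohort"))) {
    if (result$horizon < 1L) stop("model horizon must be positive", call. = FALSE)
    per_person <- result$total_cost / result$horizon
  } else if (is.numeric(result) && length(result) == 1L) {
    per_person <- result
  } else {
    stop("'result' must be a markov_cohort fit, its summary, or a scalar cost",
         call. = FALSE)
  }
  horizon <- as.integer(horizon)
  if (horizon < 0L) stop("'horizon' must be non-negative", call. = FALSE)
  if (population < 0) stop("'population' must be non-negative", call. = FALSE)
  series <- per_person * population * (1 + growth_rate)^(0:horizon)
  structure(list(per_person_annual_cost = per_person,
                 population = as.integer(population),
                 growth_rate = growth_rate,
                 series = stats::setNames(series, paste0("year_", 0:horizon))),
            class = "budget_projection")
}

#' @export
print.budget_projection <- function(x, ...) {
  cat(sprintf("Budget projection: %d people, USD %.2f/person/year, %.1f%% annual growth\n",
              x$population, x$per_person_annual_cost, 100 * x$growth_rate))
  print(round(x$series, 2))
  invisible(x)
}

#' Default categorization rules for descriptive summaries
#'
#' CD4 staging bins, the 50 copies/mL viral-load threshold, the 95-point
#' adherence threshold, and age-group breaks. Age breaks default to the
#' study groupings (< 28, 28-34, 35-42, > 42 years); pass a panel to compute
#' sample quartile edges instead.
#'
#' @param panel Optional panel with an `age` column from which quartile
#'   edges are computed.
#' @return List of rule settings, classed `categorization_rules`.
#' @export
categorization_rules <- function(panel = NULL) {
  age_breaks <- c(28, 35, 43)
  if (!is.null(panel) && "age" %in% names(panel)) {
    a <- panel$age[!duplicated(panel$patient_id)]
    age_breaks <- unique(round(stats::quantile(a, c(0.25, 0.5, 0.75),
                                               names = FALSE)))
  }
  if (any(diff(age_breaks) <= 0)) {
    stop("age breaks must be strictly increasing", call. = FALSE)
  }
  structure(list(viral_load_threshold = 50, adherence_threshold = 95,
                 age_breaks = age_breaks),
            class = "categorization_rules")
}

.pct_table <- function(f) {
  tab <- table(f)
  data.frame(category = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Descriptive summary of a panel
#'
#' Per-category counts and percentages (baseline and latest CD4 stage,
#' viral-load suppression, adherence class, gender, age group) plus
#' mean +/- SD for the continuous fields, computed over patients (baseline
#' characteristics) and over the latest available visit (current status).
#' Optional fields absent from the panel are omitted from the report.
#'
#' @param panel Long-format panel data frame.
#' @param rules A [categorization_rules()] object.
#' @return Object of class `panel_summary`: list of data frames
#'   (`categorical`) and a `continuous` table of mean/SD, plus `n_patients`.
#' @export
summarize_panel <- function(panel, rules = categorization_rules()) {
  panel <- .check_panel(panel)
  stopifnot(inherits(rules, "categorization_rules"))
  panel <- panel[order(panel$patient_id, panel$year_index), ]
  first <- panel[!duplicated(panel$patient_id), ]
  last <- panel[!duplicated(panel$patient_id, fromLast = TRUE), ]

  categorical <- list(
    baseline_cd4_stage = .pct_table(classify_cd4(first$cd4_count)),
    current_cd4_stage = .pct_table(classify_cd4(last$cd4_count)))
  continuous <- list(
    baseline_cd4 = first$cd4_count,
    current_cd4 = last$cd4_count)

  if ("viral_load" %in% names(panel)) {
    categorical$current_viral_load <- .pct_table(classify_viral_load(last$viral_load))
  }
  if ("adherence_index" %in% names(panel)) {
    categorical$adherence <- .pct_table(classify_adherence(first$adherence_index))
    continuous$adherence_index <- first$adherence_index
  }
  if ("gender" %in% names(panel)) {
    categorical$gender <- .pct_table(factor(first$gender))
  }
  if ("age" %in% names(panel)) {
    b <- rules$age_breaks
    lab <- c(sprintf("<%d", b[1]),
             sprintf("%d-%d", b[-length(b)], b[-1] - 1),
             sprintf(">%d", b[length(b)] - 1))
    categorical$age_group <- .pct_table(
      cut(first$age, c(-Inf, b, Inf), labels = lab, right = FALSE))
    continuous$age <- first$age
  }

  cont <- data.frame(
    variable = names(continuous),
    mean = round(vapply(continuous, mean, numeric(1)), 2),
    sd = round(vapply(continuous, stats::sd, numeric(1)), 2),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(n_patients = nrow(first), categorical = categorical,
                 continuous = cont),
            class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel summary: %d patients\n", x$n_patients))
  for (nm in names(x$categorical)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$categorical[[nm]], row.names = FALSE)
  }
  cat("\ncontinuous (mean +/- SD):\n")
  print(x$continuous, row.names = FALSE)
  invisible(x)
}
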