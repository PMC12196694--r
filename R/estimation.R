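# Panel layout shared by the estimator, the generator and file I/O: long
# format, one row per patient-year, columns patient_id, year_index,
# cd4_count, and optionally viral_load, age, gender, adherence_index,
# art_naive.
.check_panel <- function(panel) {
  need <- c("patient_id", "year_index", "cd4_count")
  if (!is.data.frame(panel) || !all(need %in% names(panel))) {
    stop("panel needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  dup <- duplicated(panel[c("patient_id", "year_index")])
  if (any(dup)) stop("duplicated patient-year rows in panel", call. = FALSE)
  panel
}

#' Estimate the baseline stage distribution from a panel
#'
#' Classifies each patient's year-0 CD4 count into the four stages and
#' returns the stage frequencies. When the panel carries an `art_naive`
#' column, only treatment-naive patients are used, since CD4 progression
#' differs between ART-naive and ART-experienced people.
#'
#' @param panel Long-format panel data frame (see [read_panel()]).
#' @return A [stage_vector()] of baseline stage proportions.
#' @export
estimate_baseline <- function(panel) {
  panel <- .check_panel(panel)
  if ("art_naive" %in% names(panel)) panel <- panel[as.logical(panel$art_naive), ]
  base <- panel[panel$year_index == 0L, ]
  if (nrow(base) == 0L) stop("no year-0 observations in panel", call. = FALSE)
  stage_vector(as.numeric(table(classify_cd4(base$cd4_count))) / nrow(base))
}

#' Count observed annual stage transitions
#'
#' Tabulates consecutive observed pairs: a patient seen at years `t - 1` and
#' `t` (with `t <= max_year`) contributes one count to the cell
#' (stage at `t - 1`, stage at `t`) of year `t`. Pairs spanning a gap in
#' follow-up are skipped; no interpolation is performed.
#'
#' @param panel Long-format panel data frame.
#' @param max_year Last transition year to tabulate (>= 1).
#' @return Object of class `transition_counts`: a list of 4 x 4 integer
#'   matrices indexed by year `1..max_year` (rows = origin stage).
#' @export
count_transitions <- function(panel, max_year) {
  panel <- .check_panel(panel)
  max_year <- as.integer(max_year)
  if (max_year < 1L) stop("'max_year' must be at least 1", call. = FALSE)
  panel <- panel[order(panel$patient_id, panel$year_index), ]
  stage <- as.integer(classify_cd4(panel$cd4_count))
  n <- nrow(panel)
  same <- panel$patient_id[-1L] == panel$patient_id[-n]
  consec <- panel$year_index[-1L] - panel$year_index[-n] == 1L
  to_year <- panel$year_index[-1L]
  keep <- c(same & consec & to_year <= max_year, FALSE)
  counts <- lapply(seq_len(max_year), function(y) {
    i <- which(keep & c(to_year == y, FALSE))
    m <- matrix(0L, 4L, 4L, dimnames = list(cd4_stages(), cd4_stages()))
    if (length(i)) {
      tab <- table(factor(stage[i], 1:4), factor(stage[i + 1L], 1:4))
      m[] <- as.integer(tab)
    }
    m
  })
  structure(counts, class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  for (y in seq_along(x)) {
    cat(sprintf("Year %d transition counts (rows = origin):\n", y))
    print(unclass(x)[[y]])
    cat("\n")
  }
  invisible(x)
}

#' Turn transition counts into a transition schedule
#'
#' Maximum-likelihood multinomial row proportions, optionally with a Laplace
#' pseudo-count: each row of year `t` becomes
#' `(count + smoothing) / (row total + 4 * smoothing)`. Years beyond
#' `carry_forward_from` resolve to that year's matrix through the schedule's
#' carry-forward lookup. A row with zero total and zero smoothing becomes an
#' identity row (the cohort stays put) with a warning.
#'
#' @param counts A [count_transitions()] result covering years
#'   `1..carry_forward_from` at least.
#' @param carry_forward_from Last year estimated from data (default 3).
#' @param smoothing Non-negative Laplace pseudo-count (default 0).
#' @return A [transition_schedule()] with
#'   `last_estimated_year = carry_forward_from`.
#' @export
estimate_transitions <- function(counts, carry_forward_from = 3, smoothing = 0) {
  stopifnot(inherits(counts, "transition_counts"))
  carry_forward_from <- as.integer(carry_forward_from)
  if (carry_forward_from < 1L) {
    stop("'carry_forward_from' must be at least 1", call. = FALSE)
  }
  if (carry_forward_from > length(counts)) {
    stop("counts do not cover years 1..carry_forward_from", call. = FALSE)
  }
  if (smoothing < 0) stop("'smoothing' must be non-negative", call. = FALSE)
  mats <- lapply(seq_len(carry_forward_from), function(y) {
    cm <- unclass(counts)[[y]]
    m <- matrix(0, 4L, 4L, dimnames = dimnames(cm))
    for (i in 1:4) {
      tot <- sum(cm[i, ])
      if (tot == 0 && smoothing == 0) {
        warning(sprintf(
          "no observed transitions out of %s in year %d; using identity row",
          cd4_stages()[i], y), call. = FALSE)
        m[i, i] <- 1
      } else {
        m[i, ] <- (cm[i, ] + smoothing) / (tot + 4 * smoothing)
      }
    }
    m
  })
  transition_schedule(mats, last_estimated_year = carry_forward_from)
}

#' Fit transition matrices and baseline distribution from panel data
#'
#' Convenience estimator chaining [estimate_baseline()],
#' [count_transitions()] and [estimate_transitions()] on one longitudinal
#' CD4 panel.
#'
#' @param panel Long-format panel data frame.
#' @param max_year Last transition year estimated from data (default 3);
#'   later model cycles carry this year's matrix forward.
#' @param smoothing Laplace pseudo-count passed to [estimate_transitions()].
#' @return Object of class `transition_fit`: list with `baseline`
#'   ([stage_vector()]), `counts`, `schedule` ([transition_schedule()]),
#'   `n_patients`, and `n_pairs` (consecutive pairs used per year).
#' @examples
#' panel <- simulate_panel(n_patients = 500, seed = 1)
#' fit <- fit_transitions(panel)
#' coef(fit)[[1]]
#' @export
fit_transitions <- function(panel, max_year = 3, smoothing = 0) {
  panel <- .check_panel(panel)
  counts <- count_transitions(panel, max_year)
  structure(list(
    baseline = estimate_baseline(panel),
    counts = counts,
    schedule = estimate_transitions(counts, carry_forward_from = max_year,
                                    smoothing = smoothing),
    n_patients = length(unique(panel$patient_id)),
    n_pairs = vapply(unclass(counts), sum, numeric(1))
  ), class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("Transition fit from %d patients (%s consecutive pairs by year)\n",
              x$n_patients, paste(x$n_pairs, collapse = ", ")))
  cat("Baseline stage distribution:\n")
  print(round(unclass(x$baseline), 4))
  print(x$schedule)
  invisible(x)
}

#' @export
coef.transition_fit <- function(object, ...) {
  object$schedule$matrices
}

#' Read and write longitudinal CD4 panels as delimited text
#'
#' Long format, one row per patient-year: `patient_id`, `year_index`,
#' `cd4_count`, and optionally `viral_load`, `age`, `gender`,
#' `adherence_index`, `art_naive`.
#'
#' @param file CSV path.
#' @return `read_panel()` returns the panel data frame; `write_panel()`
#'   invisibly returns `file`.
#' @export
read_panel <- function(file) {
  .check_panel(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @param panel Panel data frame to write.
#' @rdname read_panel
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(.check_panel(panel), file, row.names = FALSE)
  invisible(file)
}
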