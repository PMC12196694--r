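# Renormalization rule shared by probability vectors and matrix rows:
# printed sources round entries independently, so sums drift off 1 by up to
# ~0.01. Values are divided by their sum; |sum - 1| > warn_tol warns and
# |sum - 1| > err_tol errors.
.renormalize <- function(x, what, warn_tol = 0.02, err_tol = 0.05) {
  s <- sum(x)
  if (abs(s - 1) > err_tol) {
    stop(sprintf("%s sums to %.4f; more than %.2f away from 1", what, s, err_tol),
         call. = FALSE)
  }
  if (abs(s - 1) > warn_tol) {
    warning(sprintf("%s sums to %.4f; renormalizing", what, s), call. = FALSE)
  }
  x / s
}

#' Construct a stage-occupancy probability vector
#'
#' A distribution over the four CD4 stages (a baseline distribution or one
#' row of a cohort trace). Entries must be non-negative; the vector is
#' divided by its sum, with a warning when the raw sum deviates from 1 by
#' more than `warn_tol` and an error beyond `err_tol` (printed sources round
#' entries independently, so small drift is expected).
#'
#' @param p Numeric vector of four non-negative values, optionally named by
#'   `cd4_stages()`.
#' @param warn_tol,err_tol Tolerances on `|sum(p) - 1|` for warning/error.
#' @return Named numeric vector of class `stage_vector`, summing to 1.
#' @examples
#' stage_vector(c(0.39, 0.22, 0.16, 0.23))
#' @export
stage_vector <- function(p, warn_tol = 0.02, err_tol = 0.05) {
  p <- .as_stage_values(p, "stage vector")
  if (any(p < 0)) stop("stage probabilities must be non-negative", call. = FALSE)
  if (sum(p) <= 0) stop("stage vector must have positive mass", call. = FALSE)
  p <- .renormalize(p, "stage vector", warn_tol, err_tol)
  structure(p, class = "stage_vector")
}

# coerce a length-4 vector to stage order; accepts unnamed (assumed ordered)
.as_stage_values <- function(x, what) {
  if (!is.numeric(x) || length(x) != 4L || anyNA(x)) {
    stop(sprintf("%s must be 4 non-missing numeric values", what), call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), cd4_stages())) {
      stop(sprintf("%s names must be exactly %s", what,
                   paste(cd4_stages(), collapse = ", ")), call. = FALSE)
    }
    x <- x[cd4_stages()]
  }
  stats::setNames(as.numeric(x), cd4_stages())
}

#' Construct a utility schedule
#'
#' One QALY weight per CD4 stage, each in \[0, 1\] (0 = death, 1 = perfect
#' health). A person spending a year with occupancy spread over stages
#' accrues the occupancy-weighted mean utility as QALYs for that year.
#'
#' @param u Numeric vector of four utilities in \[0, 1\], optionally named.
#' @return Named numeric vector of class `utility_schedule`.
#' @examples
#' utility_schedule(c(0.67, 0.70, 0.71, 0.73))
#' @export
utility_schedule <- function(u) {
  u <- .as_stage_values(u, "utility schedule")
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]", call. = FALSE)
  structure(u, class = "utility_schedule")
}

#' Construct a per-stage cost schedule
#'
#' Holds the annual cost of care per person in USD for each CD4 stage, split
#' into the initial cost (first year of care, accrued at model time 0) and
#' the incremental cost (each subsequent year, accrued at times 1..horizon).
#'
#' @param initial Numeric vector of four non-negative first-year costs (USD).
#' @param incremental Numeric vector of four non-negative subsequent-year
#'   costs (USD).
#' @return Object of class `cost_schedule`: a list with elements `initial`
#'   and `incremental`, each named by stage.
#' @examples
#' cost_schedule(initial = c(2147.37, 2118.01, 2118.01, 2118.01),
#'               incremental = c(2025.54, 1440.75, 1406.49, 1400.78))
#' @export
cost_schedule <- function(initial, incremental) {
  initial <- .as_stage_values(initial, "initial costs")
  incremental <- .as_stage_values(incremental, "incremental costs")
  if (any(initial < 0) || any(incremental < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  structure(list(initial = initial, incremental = incremental),
            class = "cost_schedule")
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Per-stage annual cost schedule (USD)\n")
  print(round(rbind(initial = x$initial, incremental = x$incremental), 2))
  invisible(x)
}

#' Construct a year-indexed transition schedule
#'
#' A set of 4 x 4 row-stochastic matrices, one per annual cycle, with rows
#' indexing the origin stage and columns the destination stage. Cycles beyond
#' the last supplied year reuse the last year's matrix (carry-forward), the
#' standard device when panel follow-up is shorter than the model horizon.
#' Each row is renormalized on construction under the same warn/error rule as
#' [stage_vector()].
#'
#' @param matrices List of 4 x 4 numeric matrices, element `t` giving the
#'   transition probabilities for cycle `t` (year `t-1` to year `t`).
#' @param last_estimated_year Last cycle with its own matrix; defaults to
#'   `length(matrices)`.
#' @param warn_tol,err_tol Row-sum tolerances passed to the renormalizer.
#' @return Object of class `transition_schedule`.
#' @seealso [transition_matrix()] for carry-forward lookup.
#' @export
transition_schedule <- function(matrices, last_estimated_year = length(matrices),
                                warn_tol = 0.02, err_tol = 0.05) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    stop("'matrices' must be a non-empty list of 4 x 4 matrices", call. = FALSE)
  }
  last_estimated_year <- as.integer(last_estimated_year)
  if (last_estimated_year < 1L || last_estimated_year > length(matrices)) {
    stop("'last_estimated_year' must index a supplied matrix", call. = FALSE)
  }
  matrices <- lapply(seq_along(matrices), function(y) {
    m <- matrices[[y]]
    if (!is.matrix(m) || !all(dim(m) == c(4L, 4L)) || anyNA(m)) {
      stop(sprintf("matrix for year %d must be 4 x 4 with no missing values", y),
           call. = FALSE)
    }
    if (any(m < 0)) {
      stop(sprintf("matrix for year %d has negative entries", y), call. = FALSE)
    }
    for (i in 1:4) {
      m[i, ] <- .renormalize(m[i, ], sprintf("year %d row %s", y, cd4_stages()[i]),
                             warn_tol, err_tol)
    }
    dimnames(m) <- list(cd4_stages(), cd4_stages())
    m
  })
  structure(list(matrices = matrices, last_estimated_year = last_estimated_year),
            class = "transition_schedule")
}

#' Look up the transition matrix for a model cycle
#'
#' Cycles beyond `last_estimated_year` resolve to the matrix of
#' `last_estimated_year` (carry-forward).
#'
#' @param schedule A [transition_schedule()].
#' @param year 1-based cycle number (>= 1).
#' @return A 4 x 4 row-stochastic matrix with stage dimnames.
#' @export
transition_matrix <- function(schedule, year) {
  stopifnot(inherits(schedule, "transition_schedule"))
  year <- as.integer(year)
  if (length(year) != 1L || is.na(year) || year < 1L) {
    stop("'year' must be a single integer >= 1", call. = FALSE)
  }
  schedule$matrices[[min(year, schedule$last_estimated_year)]]
}

#' @export
print.transition_schedule <- function(x, digits = 4, ...) {
  cat(sprintf("Transition schedule: %d matrix(es), carry-forward after year %d\n",
              length(x$matrices), x$last_estimated_year))
  for (y in seq_along(x$matrices)) {
    cat(sprintf("\nYear %d (rows = origin stage):\n", y))
    print(round(x$matrices[[y]], digits))
  }
  invisible(x)
}

#' Read and write transition matrices as delimited text
#'
#' One CSV per model year: a header row naming the four destination stages,
#' a first column naming the origin stages (rows = origin, columns =
#' destination). Stage names must match `cd4_stages()` exactly. Rows are
#' renormalized on read under the usual warn/error rule.
#'
#' @param files Character vector of per-year CSV paths, in year order.
#' @param last_estimated_year Passed to [transition_schedule()].
#' @param warn_tol,err_tol Row-sum tolerances.
#' @return `read_transition_schedule()` returns a [transition_schedule()];
#'   `write_transition_schedule()` invisibly returns the paths written.
#' @export
read_transition_schedule <- function(files, last_estimated_year = length(files),
                                     warn_tol = 0.02, err_tol = 0.05) {
  mats <- lapply(files, function(f) {
    d <- utils::read.csv(f, row.names = 1, check.names = FALSE)
    m <- as.matrix(d)
    if (!identical(rownames(m), cd4_stages()) ||
        !identical(colnames(m), cd4_stages())) {
      stop(sprintf("'%s' must name rows and columns exactly %s", f,
                   paste(cd4_stages(), collapse = ", ")), call. = FALSE)
    }
    m
  })
  transition_schedule(mats, last_estimated_year, warn_tol, err_tol)
}

#' @param schedule A [transition_schedule()] to write.
#' @param dir Output directory for `transitions_year<y>.csv` files.
#' @rdname read_transition_schedule
#' @export
write_transition_schedule <- function(schedule, dir) {
  stopifnot(inherits(schedule, "transition_schedule"))
  paths <- vapply(seq_along(schedule$matrices), function(y) {
    p <- file.path(dir, sprintf("transitions_year%d.csv", y))
    utils::write.csv(round(schedule$matrices[[y]], 6), p)
    p
  }, character(1))
  invisible(paths)
}

#' Read and write a cost schedule as delimited text
#'
#' Four rows (one per stage) with columns `stage`, `initial`, `incremental`;
#' monetary values in USD at 2-decimal precision.
#'
#' @param file CSV path.
#' @return `read_cost_schedule()` returns a [cost_schedule()];
#'   `write_cost_schedule()` invisibly returns `file`.
#' @export
read_cost_schedule <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("stage", "initial", "incremental")
  if (!all(need %in% names(d))) {
    stop("cost schedule file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cost_schedule(stats::setNames(d$initial, d$stage),
                stats::setNames(d$incremental, d$stage))
}

#' @param schedule A [cost_schedule()] to write.
#' @rdname read_cost_schedule
#' @export
write_cost_schedule <- function(schedule, file) {
  stopifnot(inherits(schedule, "cost_schedule"))
  utils::write.csv(data.frame(stage = cd4_stages(),
                              initial = round(schedule$initial, 2),
                              incremental = round(schedule$incremental, 2)),
                   file, row.names = FALSE)
  invisible(file)
}
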