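# default transition set for the generator: the packaged matrices, loaded
# without re-announcing their (documented) row renormalization
.default_transitions <- function() {
  suppressWarnings(load_fixtures("table2"))
}

#' Simulate a synthetic longitudinal CD4 panel
#'
#' Generates a cohort with the statistical structure the economic analysis
#' assumes, so every estimator in the package can be exercised without
#' patient-level data. Each patient draws a baseline stage from `baseline`
#' and an annual stage path from `transitions` (with carry-forward past the
#' last estimated year). Observable quantities are then layered on:
#' \itemize{
#'   \item CD4 count: uniform within the occupied stage's bin, the top bin
#'     capped at 1500 cells/uL;
#'   \item viral load: below 50 copies/mL with probability
#'     `undetectable_fraction` (drawn uniform on \[0, 50)), otherwise uniform
#'     on \[50, 10000\];
#'   \item adherence index: one per patient, Normal(`adherence_mean`,
#'     `adherence_sd`) hard-truncated to \[0, 100\];
#'   \item age and gender: patient-level covariates for descriptive
#'     summaries (ages centred in the mid-30s, ~89% male, mirroring the
#'     served clinic population).
#' }
#' Defaults reproduce the published study conditions: 237 ART-naive
#' patients, baseline stage distribution (0.39, 0.22, 0.16, 0.23), the
#' packaged year-specific transition matrices, 95.4% undetectability, and
#' adherence ~ N(89.97, 11.98^2).
#'
#' @param n_patients Number of patients (default 237).
#' @param years Follow-up years after baseline (default 5).
#' @param baseline [stage_vector()] of baseline stage probabilities.
#' @param transitions [transition_schedule()] driving the stage paths.
#' @param undetectable_fraction Probability a visit's viral load is < 50
#'   copies/mL (default 0.954).
#' @param adherence_mean,adherence_sd Adherence-index distribution before
#'   truncation to \[0, 100\] (defaults 89.97 and 11.98).
#' @param dropout_rate Per-year probability a patient leaves care; a dropout
#'   truncates the trajectory (default 0).
#' @param seed Optional integer seed; fixed seed gives identical panels.
#' @return Long-format panel data frame (see [read_panel()]) with
#'   `art_naive = TRUE` throughout.
#' @examples
#' panel <- simulate_panel(n_patients = 100, seed = 42)
#' head(panel)
#' @export
simulate_panel <- function(n_patients = 237, years = 5,
                           baseline = load_fixtures("table1")$baseline,
                           transitions = .default_transitions(),
                           undetectable_fraction = 0.954,
                           adherence_mean = 89.97, adherence_sd = 11.98,
                           dropout_rate = 0, seed = NULL) {
  n_patients <- as.integer(n_patients)
  years <- as.integer(years)
  stopifnot(n_patients >= 1L, years >= 0L,
            inherits(transitions, "transition_schedule"))
  if (!inherits(baseline, "stage_vector")) baseline <- stage_vector(baseline)
  if (undetectable_fraction < 0 || undetectable_fraction > 1 ||
      dropout_rate < 0 || dropout_rate > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  # stage paths: n_patients x (years + 1)
  path <- matrix(NA_integer_, n_patients, years + 1L)
  path[, 1L] <- sample.int(4L, n_patients, replace = TRUE,
                           prob = unclass(baseline))
  for (t in seq_len(years)) {
    m <- transition_matrix(transitions, t)
    for (s in 1:4) {
      idx <- which(path[, t] == s)
      if (length(idx)) {
        path[idx, t + 1L] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = m[s, ])
      }
    }
  }

  # follow-up length: first dropout truncates the trajectory
  last_year <- rep(years, n_patients)
  if (dropout_rate > 0 && years > 0L) {
    drops <- matrix(stats::runif(n_patients * years) < dropout_rate,
                    n_patients, years)
    first <- apply(drops, 1, function(z) if (any(z)) which(z)[1L] else NA_integer_)
    last_year <- ifelse(is.na(first), years, first - 1L)
  }

  ai <- pmin(100, pmax(0, stats::rnorm(n_patients, adherence_mean, adherence_sd)))
  age <- round(pmin(80, pmax(18, stats::rnorm(n_patients, 36, 10))))
  gender <- ifelse(stats::runif(n_patients) < 0.889, "male", "female")

  rows <- rep(seq_len(n_patients), last_year + 1L)
  year <- unlist(lapply(last_year, seq.int, from = 0L), use.names = FALSE)
  stage <- path[cbind(rows, year + 1L)]
  lo <- c(0, 200, 350, 500)[stage]
  hi <- c(200, 350, 500, 1500)[stage]
  cd4 <- stats::runif(length(stage), lo, hi)
  undet <- stats::runif(length(stage)) < undetectable_fraction
  vl <- ifelse(undet, stats::runif(length(stage), 0, 50),
               stats::runif(length(stage), 50, 10000))

  data.frame(patient_id = sprintf("P%05d", rows),
             year_index = year,
             cd4_count = cd4,
             viral_load = vl,
             age = age[rows],
             gender = gender[rows],
             adherence_index = ai[rows],
             art_naive = TRUE,
             stringsAsFactors = FALSE)
}

#' Thin a panel by deleting follow-up observations at random
#'
#' Each non-baseline observation is independently deleted with probability
#' `missing_rate`; year-0 rows are always kept. Used to exercise the
#' consecutive-pair gap handling of [count_transitions()].
#'
#' @param panel Long-format panel data frame.
#' @param missing_rate Deletion probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return The thinned panel.
#' @export
degrade_panel <- function(panel, missing_rate, seed = NULL) {
  panel <- .check_panel(panel)
  if (missing_rate < 0 || missing_rate > 1) {
    stop("'missing_rate' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  drop <- panel$year_index > 0L & stats::runif(nrow(panel)) < missing_rate
  panel[!drop, , drop = FALSE]
}
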