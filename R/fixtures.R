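#' Load the packaged model-input fixtures
#'
#' Two fixture sets ship with the package, transcribing the published model
#' inputs for ART care at a Mexico City specialized HIV clinic:
#' \describe{
#'   \item{`"table1"`}{per-stage baseline probabilities, utility scores, and
#'     initial (first-year) / incremental (subsequent-year) USD costs;}
#'   \item{`"table2"`}{year-specific 4 x 4 stage-transition matrices for
#'     care years 1-3, with year 3 carried forward to later cycles.}
#' }
#' Printed probability rows are rounded independently at source and can sum
#' to 0.99-1.01; they are renormalized on load, with a warning for any row
#' off 1 by more than 0.005 so the adjustment is visible.
#'
#' @param name `"table1"` or `"table2"`.
#' @return For `"table1"`, a list with `baseline` ([stage_vector()]),
#'   `utilities` ([utility_schedule()]) and `costs` ([cost_schedule()]).
#'   For `"table2"`, a [transition_schedule()] with
#'   `last_estimated_year = 3`.
#' @examples
#' load_fixtures("table1")$utilities
#' @export
load_fixtures <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  if (name == "table1") {
    f <- system.file("extdata", "table1_model_inputs.csv", package = "artcua",
                     mustWork = TRUE)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    stopifnot(identical(d$stage, cd4_stages()))
    list(baseline = stage_vector(stats::setNames(d$baseline_probability, d$stage),
                                 warn_tol = 0.005),
         utilities = utility_schedule(stats::setNames(d$utility, d$stage)),
         costs = cost_schedule(stats::setNames(d$initial_cost, d$stage),
                               stats::setNames(d$incremental_cost, d$stage)))
  } else {
    files <- vapply(1:3, function(y) {
      system.file("extdata", sprintf("table2_transitions_year%d.csv", y),
                  package = "artcua", mustWork = TRUE)
    }, character(1))
    read_transition_schedule(files, last_estimated_year = 3, warn_tol = 0.005)
  }
}
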