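#' CD4 immunological stage labels
#'
#' The four WHO-style immunological strata used as Markov states, in order
#' of increasing CD4 count: `CD4_LT_200` (< 200 cells/uL), `CD4_200_349`
#' (200-349), `CD4_350_499` (350-499) and `CD4_GE_500` (>= 500). The
#' half-open intervals \[0, 200), \[200, 350), \[350, 500), \[500, Inf)
#' partition the non-negative CD4 axis.
#'
#' @return Character vector of the four stage labels, worst to best.
#' @export
cd4_stages <- function() {
  c("CD4_LT_200", "CD4_200_349", "CD4_350_499", "CD4_GE_500")
}

# lower bin edges shared by classify_cd4() and the synthetic generator
.cd4_breaks <- c(0, 200, 350, 500)

#' Classify CD4 counts into immunological stages
#'
#' Bins are half-open on the right, so a count of exactly 200 falls in
#' `CD4_200_349` and exactly 500 in `CD4_GE_500`.
#'
#' @param count Numeric vector of CD4 counts (cells/uL), all >= 0.
#' @return Factor with levels `cd4_stages()`, same length as `count`.
#' @examples
#' classify_cd4(c(199, 200, 350, 502))
#' @export
classify_cd4 <- function(count) {
  if (!is.numeric(count) || anyNA(count)) {
    stop("'count' must be numeric with no missing values", call. = FALSE)
  }
  if (any(count < 0)) {
    stop("CD4 counts must be non-negative", call. = FALSE)
  }
  idx <- findInterval(count, .cd4_breaks)
  factor(cd4_stages()[idx], levels = cd4_stages())
}

#' Classify viral load as undetectable or unsuppressed
#'
#' Plasma HIV RNA below 50 copies/mL is classed `UNDETECTABLE`; 50 copies/mL
#' or more is `UNSUPPRESSED`. The boundary value 50 itself counts as
#' unsuppressed, so the two categories are exhaustive.
#'
#' @param copies Numeric vector of viral loads (copies/mL), all >= 0.
#' @return Factor with levels `UNDETECTABLE`, `UNSUPPRESSED`.
#' @export
classify_viral_load <- function(copies) {
  if (!is.numeric(copies) || anyNA(copies)) {
    stop("'copies' must be numeric with no missing values", call. = FALSE)
  }
  if (any(copies < 0)) {
    stop("viral loads must be non-negative", call. = FALSE)
  }
  factor(ifelse(copies < 50, "UNDETECTABLE", "UNSUPPRESSED"),
         levels = c("UNDETECTABLE", "UNSUPPRESSED"))
}

#' Classify an adherence index as adherent or non-adherent
#'
#' Self-reported adherence scores of 95 or more (on a 0-100 scale) are
#' classed `ADHERENT`, below 95 `NON_ADHERENT`.
#'
#' @param ai Numeric vector of adherence indices in \[0, 100\].
#' @return Factor with levels `ADHERENT`, `NON_ADHERENT`.
#' @export
classify_adherence <- function(ai) {
  if (!is.numeric(ai) || anyNA(ai)) {
    stop("'ai' must be numeric with no missing values", call. = FALSE)
  }
  if (any(ai < 0 | ai > 100)) {
    stop("adherence indices must lie in [0, 100]", call. = FALSE)
  }
  factor(ifelse(ai >= 95, "ADHERENT", "NON_ADHERENT"),
         levels = c("ADHERENT", "NON_ADHERENT"))
}
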