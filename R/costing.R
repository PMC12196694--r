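#' Convert monetary amounts to USD
#'
#' MXN amounts are divided by the pesos-per-dollar exchange rate; USD
#' amounts pass through unchanged.
#'
#' @param amount Numeric vector of non-negative amounts.
#' @param currency Character vector (recycled) of currency codes, each
#'   `"MXN"` or `"USD"`.
#' @param mxn_per_usd Exchange rate, pesos per dollar (default 18.22, the
#'   2024 average interbank rate).
#' @return Numeric vector of USD amounts.
#' @examples
#' convert_to_usd(18.22, "MXN")  # 1
#' @export
convert_to_usd <- function(amount, currency, mxn_per_usd = 18.22) {
  if (!is.numeric(amount) || anyNA(amount)) {
    stop("'amount' must be numeric with no missing values", call. = FALSE)
  }
  if (any(amount < 0)) stop("amounts must be non-negative", call. = FALSE)
  if (mxn_per_usd <= 0) stop("'mxn_per_usd' must be positive", call. = FALSE)
  currency <- rep_len(as.character(currency), length(amount))
  bad <- setdiff(unique(currency), c("MXN", "USD"))
  if (length(bad)) {
    stop("unknown currency code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(currency == "MXN", amount / mxn_per_usd, amount)
}

#' Validate a resource-use line-item table
#'
#' Each line item is one health resource (drug, laboratory study, medical
#' visit, ...) with a unit cost `UC`, an annual frequency of use `F` and the
#' proportion `P` of people using it, so its annual cost contribution is
#' `UC x F x P`. Items are restricted to stages and to the initial or
#' subsequent phase of care.
#'
#' @param items Data frame with columns `name`, `unit_cost`, `currency`
#'   (`MXN`/`USD`), `annual_frequency`, `proportion_using`, `stages`
#'   (semicolon-separated stage labels, or `ALL`), `phase` (`INITIAL`,
#'   `SUBSEQUENT` or `BOTH`).
#' @return The validated data frame, classed `resource_items`.
#' @export
resource_items <- function(items) {
  need <- c("name", "unit_cost", "currency", "annual_frequency",
            "proportion_using", "stages", "phase")
  if (!is.data.frame(items) || !all(need %in% names(items))) {
    stop("resource items need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(items$unit_cost < 0) || any(items$annual_frequency < 0)) {
    stop("unit costs and frequencies must be non-negative", call. = FALSE)
  }
  if (any(items$proportion_using < 0 | items$proportion_using > 1)) {
    stop("proportions using must lie in [0, 1]", call. = FALSE)
  }
  if (!all(items$phase %in% c("INITIAL", "SUBSEQUENT", "BOTH"))) {
    stop("phase must be INITIAL, SUBSEQUENT or BOTH", call. = FALSE)
  }
  for (s in items$stages) {
    labs <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (!identical(labs, "ALL") && !all(labs %in% cd4_stages())) {
      stop("unknown stage label in 'stages': ", s, call. = FALSE)
    }
  }
  class(items) <- c("resource_items", class(items))
  items
}

.item_applies <- function(item_stages, stage) {
  labs <- strsplit(item_stages, ";", fixed = TRUE)[[1]]
  identical(labs, "ALL") || stage %in% labs
}

#' Annual per-person cost of one stage and phase from line items
#'
#' Sums `unit_cost x annual_frequency x proportion_using` over the items
#' applicable to the given stage and phase, converting to USD.
#'
#' @param items A [resource_items()] table.
#' @param stage One of `cd4_stages()`.
#' @param phase `"INITIAL"` (first year of care) or `"SUBSEQUENT"`.
#' @param mxn_per_usd Exchange rate for MXN-priced items.
#' @return Annual cost in USD (scalar).
#' @examples
#' drug <- resource_items(data.frame(
#'   name = "BIC/FTC/TAF", unit_cost = 94.40, currency = "USD",
#'   annual_frequency = 12, proportion_using = 1, stages = "ALL",
#'   phase = "BOTH"))
#' stage_annual_cost(drug, "CD4_GE_500", "SUBSEQUENT")  # 1132.80
#' @export
stage_annual_cost <- function(items, stage, phase = c("INITIAL", "SUBSEQUENT"),
                              mxn_per_usd = 18.22) {
  items <- resource_items(items)
  stage <- match.arg(stage, cd4_stages())
  phase <- match.arg(phase)
  keep <- vapply(seq_len(nrow(items)), function(i) {
    items$phase[i] %in% c(phase, "BOTH") && .item_applies(items$stages[i], stage)
  }, logical(1))
  if (!any(keep)) return(0)
  it <- items[keep, , drop = FALSE]
  sum(convert_to_usd(it$unit_cost, it$currency, mxn_per_usd) *
        it$annual_frequency * it$proportion_using)
}

#' Assemble a per-stage cost schedule
#'
#' Two input modes, exactly one of which must be used. Direct mode passes
#' per-stage initial and incremental totals through unchanged (the published
#' model inputs are of this form). Line-item mode computes every stage/phase
#' cell from a resource-use table via [stage_annual_cost()], applying the
#' cost equation `sum(UC x F x P)`.
#'
#' @param items Optional [resource_items()] table (line-item mode).
#' @param initial,incremental Optional per-stage USD totals (direct mode).
#' @param mxn_per_usd Exchange rate for MXN-priced items.
#' @return A [cost_schedule()].
#' @export
build_cost_schedule <- function(items = NULL, initial = NULL,
                                incremental = NULL, mxn_per_usd = 18.22) {
  direct <- !is.null(initial) || !is.null(incremental)
  if (is.null(items) == !direct) {
    stop("supply either 'items' or both 'initial' and 'incremental', not both",
         call. = FALSE)
  }
  if (direct) {
    if (is.null(initial) || is.null(incremental)) {
      stop("direct mode needs both 'initial' and 'incremental'", call. = FALSE)
    }
    return(cost_schedule(initial, incremental))
  }
  items <- resource_items(items)
  init <- vapply(cd4_stages(), stage_annual_cost, numeric(1), items = items,
                 phase = "INITIAL", mxn_per_usd = mxn_per_usd)
  incr <- vapply(cd4_stages(), stage_annual_cost, numeric(1), items = items,
                 phase = "SUBSEQUENT", mxn_per_usd = mxn_per_usd)
  cost_schedule(init, incr)
}

#' Decompose a cost schedule into a drug item plus residual care items
#'
#' Splits each stage/phase total into a single ART drug line item (unit cost
#' per monthly dispensation, 12 dispensations per year, used by everyone in
#' every stage) plus one residual "other care" item per stage and phase
#' carrying the remainder. Useful for one-way sensitivity analysis on the
#' drug price when only stage totals, not the underlying resource table, are
#' available.
#'
#' @param schedule A [cost_schedule()] whose every cell is at least the
#'   annual drug cost.
#' @param monthly_cost Drug cost per monthly dispensation in USD
#'   (default 94.40).
#' @param drug_name Line-item name for the drug.
#' @return A [resource_items()] table reproducing `schedule` through
#'   [build_cost_schedule()].
#' @export
drug_residual_items <- function(schedule, monthly_cost = 94.40,
                                drug_name = "ART drug") {
  stopifnot(inherits(schedule, "cost_schedule"))
  annual_drug <- 12 * monthly_cost
  resid <- c(schedule$initial, schedule$incremental) - annual_drug
  if (any(resid < 0)) {
    stop("annual drug cost exceeds a stage total; cannot decompose", call. = FALSE)
  }
  items <- data.frame(
    name = c(drug_name,
             paste0("other care ", rep(c("initial ", "subsequent "), each = 4),
                    cd4_stages())),
    unit_cost = c(monthly_cost, schedule$initial - annual_drug,
                  schedule$incremental - annual_drug),
    currency = "USD",
    annual_frequency = c(12, rep(1, 8)),
    proportion_using = 1,
    stages = c("ALL", rep(cd4_stages(), 2)),
    phase = c("BOTH", rep(c("INITIAL", "SUBSEQUENT"), each = 4)),
    stringsAsFactors = FALSE, row.names = NULL)
  resource_items(items)
}

#' Read and write resource-use tables as delimited text
#'
#' Columns as documented in [resource_items()].
#'
#' @param file CSV path.
#' @return `read_resource_items()` returns a [resource_items()] table;
#'   `write_resource_items()` invisibly returns `file`.
#' @export
read_resource_items <- function(file) {
  resource_items(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @param items A [resource_items()] table to write.
#' @rdname read_resource_items
#' @export
write_resource_items <- function(items, file) {
  items <- resource_items(items)
  utils::write.csv(as.data.frame(items), file, row.names = FALSE)
  invisible(file)
}
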