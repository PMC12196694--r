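#' Read a run configuration from YAML or JSON
#'
#' Recognized keys (all optional, with packaged defaults): `horizon_years`,
#' `discount_rate_costs`, `discount_rate_qalys`, `wtp_per_qaly`,
#' `exchange_rate_mxn_per_usd`, `panel` (path to a longitudinal CD4 panel;
#' when present, baseline and transitions are estimated from it instead of
#' the packaged fixtures), `max_estimated_year`, `resources` (path to a
#' resource-use table; when present, stage costs are built from line items),
#' `seed`, `psa` (`n_iterations`, `variation`), `tornado` (`variation`,
#' `parameters`), `out_dir`.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file, call. = FALSE)
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::read_json(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  if (!is.list(cfg)) stop("config must be a mapping of keys to values", call. = FALSE)
  cfg
}

.cfg_get <- function(cfg, key, default) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Run the full cost-utility pipeline
#'
#' Executes the analysis end to end from a configuration: (optionally)
#' estimate baseline and transition matrices from a panel, build the cost
#' schedule (from resource line items or the packaged stage totals), run the
#' Markov cohort model, summarize it against the willingness-to-pay
#' threshold, and optionally run the probabilistic and tornado sensitivity
#' analyses. When `out_dir` is set, the cohort trace, a JSON summary, any
#' sensitivity outputs, and a manifest sufficient to reproduce the run
#' (configuration values, seed, package version, timestamp) are written
#' there as delimited text/JSON.
#'
#' @param config Path to a YAML/JSON configuration (see
#'   [read_run_config()]) or an equivalent named list. An empty list runs
#'   the packaged base case.
#' @return Invisibly, a list with the `markov_cohort` fit (`model`), its
#'   `summary`, any `psa`/`tornado` results, and the paths written
#'   (`paths`).
#' @examples
#' res <- run_pipeline(list(horizon_years = 5))
#' res$summary
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  if (!is.list(cfg)) stop("'config' must be a path or a list", call. = FALSE)

  seed <- .cfg_get(cfg, "seed", NULL)
  if (!is.null(seed)) set.seed(as.integer(seed))
  horizon <- .cfg_get(cfg, "horizon_years", 5)
  rate <- .cfg_get(cfg, "exchange_rate_mxn_per_usd", 18.22)

  tab1 <- load_fixtures("table1")
  utilities <- tab1$utilities

  if (!is.null(cfg$panel)) {
    fit <- fit_transitions(read_panel(cfg$panel),
                           max_year = .cfg_get(cfg, "max_estimated_year", 3))
    baseline <- fit$baseline
    transitions <- fit$schedule
  } else {
    baseline <- tab1$baseline
    transitions <- load_fixtures("table2")
  }

  items <- NULL
  if (!is.null(cfg$resources)) {
    items <- read_resource_items(cfg$resources)
    costs <- build_cost_schedule(items = items, mxn_per_usd = rate)
  } else {
    costs <- tab1$costs
  }

  model <- markov_cohort(baseline, transitions, costs, utilities,
                         horizon = horizon,
                         discount_costs = .cfg_get(cfg, "discount_rate_costs", 0.05),
                         discount_qalys = .cfg_get(cfg, "discount_rate_qalys", 0.05),
                         wtp = .cfg_get(cfg, "wtp_per_qaly", 13790))
  smry <- summary(model)

  psa <- NULL
  if (!is.null(cfg$psa)) {
    psa <- run_psa(baseline, transitions, costs, utilities,
                   n_iterations = .cfg_get(cfg$psa, "n_iterations", 10000),
                   variation = .cfg_get(cfg$psa, "variation", 0.07),
                   seed = .cfg_get(cfg$psa, "seed", seed),
                   horizon = horizon,
                   discount_costs = model$discount_costs,
                   discount_qalys = model$discount_qalys, wtp = model$wtp)
  }
  torn <- NULL
  if (!is.null(cfg$tornado)) {
    torn <- tornado(baseline, transitions, costs, utilities,
                    parameters = .cfg_get(cfg$tornado, "parameters", NULL),
                    variation = .cfg_get(cfg$tornado, "variation", 0.07),
                    items = items, horizon = horizon,
                    discount_costs = model$discount_costs,
                    discount_qalys = model$discount_qalys,
                    mxn_per_usd = rate)
  }

  paths <- character(0)
  out_dir <- .cfg_get(cfg, "out_dir", NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(trace = write_trace(model, file.path(out_dir, "trace.csv")))
    sfile <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(
      total_cost = round(smry$total_cost, 2),
      total_qalys = round(smry$total_qalys, 4),
      cost_per_qaly = round(smry$cost_per_qaly, 2),
      below_wtp = smry$below_wtp, wtp = smry$wtp),
      sfile, auto_unbox = TRUE)
    paths <- c(paths, summary = sfile)
    if (!is.null(psa)) {
      paths <- c(paths,
                 psa = write_psa_samples(psa, file.path(out_dir, "psa_samples.csv")))
    }
    if (!is.null(torn)) {
      paths <- c(paths,
                 tornado = write_tornado(torn, file.path(out_dir, "tornado.csv")))
    }
    mfile <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(list(
      package = "artcua",
      version = as.character(utils::packageVersion("artcua")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = seed, config = cfg),
      mfile, auto_unbox = TRUE, null = "null")
    paths <- c(paths, manifest = mfile)
  }

  invisible(list(model = model, summary = smry, psa = psa, tornado = torn,
                 paths = paths))
}
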