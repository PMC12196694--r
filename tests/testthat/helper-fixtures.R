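# Shared fixture loaders and small builders. Fixture transition rows are
# rounded at source, so loading them legitimately warns; tests that are not
# about the warnings load them quietly.

tab1 <- function() load_fixtures("table1")

tab2 <- function() suppressWarnings(load_fixtures("table2"))

base_case <- function(...) {
  t1 <- tab1()
  markov_cohort(t1$baseline, tab2(), t1$costs, t1$utilities, ...)
}

identity_schedule <- function(years = 1) {
  transition_schedule(rep(list(diag(4)), years))
}

# random row-stochastic schedule for property tests
random_schedule <- function(years = 3) {
  transition_schedule(lapply(seq_len(years), function(y) {
    m <- matrix(stats::runif(16, 0.01, 1), 4, 4)
    sweep(m, 1, rowSums(m), "/")
  }))
}

random_stage_vector <- function() {
  p <- stats::runif(4, 0.01, 1)
  stage_vector(p / sum(p))
}

# minimal long-format panel from per-patient CD4 trajectories
panel_from_cd4 <- function(trajectories, start_year = 0) {
  do.call(rbind, lapply(seq_along(trajectories), function(i) {
    cd4 <- trajectories[[i]]
    data.frame(patient_id = sprintf("P%03d", i),
               year_index = seq_along(cd4) - 1 + start_year,
               cd4_count = cd4)
  }))
}
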