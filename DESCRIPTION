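Package: artcua
Title: Cost-Utility Analysis of Antiretroviral Therapy with a CD4-Stage
    Markov Cohort Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-state Markov cohort model of immunological progression
    in people living with HIV on antiretroviral therapy, with discounted
    cost and quality-adjusted life-year (QALY) accrual, estimation of
    year-specific transition matrices from longitudinal CD4 panel data,
    stage-cost construction from resource-use line items, probabilistic
    and one-way (tornado) sensitivity analysis, clinic-level budget
    projection, and a synthetic cohort generator for fully reproducible
    testing without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
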