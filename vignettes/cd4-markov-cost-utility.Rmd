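---
title: "Methods: a CD4-stage Markov cohort model for ART cost-utility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CD4-stage Markov cohort model for ART cost-utility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`artcua` implements a clinic-perspective cost–utility evaluation of
antiretroviral therapy (ART) for people living with HIV. This vignette is
the package's account of the model, the estimation and sensitivity
machinery around it, and the design choices taken where more than one
reasonable construction existed.

## The decision model

The health states are the four WHO immunological strata of CD4 count:
`<200`, `200–349`, `350–499` and `≥500` cells/μL, half-open on the right
(a count of exactly 200 belongs to `200–349`, exactly 500 to `≥500`). A
cohort is a probability vector π over the four states. Each annual cycle
multiplies it by a year-specific row-stochastic matrix P<sub>t</sub>
(rows = origin stage); after the last year for which a matrix was
estimated, that matrix is carried forward unchanged. Death is not a model
state — over a five-year horizon in a suppressed, mostly young population
the model treats mortality as negligible, and mass is conserved exactly.
The engine nevertheless handles absorbing rows without special-casing, so
users can add one by supplying a unit row.

**Accrual convention.** Costs and utilities are evaluated at the
*horizon + 1* model times t = 0..T: the baseline state and each
post-transition state. The stage-weighted *initial* cost (first year of
care) is accrued at t = 0 undiscounted; stage-weighted *incremental* costs
(subsequent years) at t = 1..T and stage-weighted utilities at t = 0..T
are discounted by (1+r)<sup>−t</sup>. No half-cycle correction is applied.
This is the one convention exposed (as an explicit design choice rather
than an option flag): with per-stage utilities capped at 0.73, any
T-evaluation convention over five years could never exceed 5 × 0.73 = 3.65
QALYs, whereas the six-evaluation convention reproduces the published
five-year totals of this model class; it is therefore the convention the
reference analysis must have used. Whether that analysis also discounted
the t = 0 accrual cannot be determined from the published totals; ours
does not, which is the conventional choice (period-0 accruals are current
spending).

**Discounting.** Both costs and health benefits default to 5 %/year, the
rate recommended by the Mexican guide for economic evaluations; both rates
are independently settable in `[0, 1)`. The willingness-to-pay threshold
defaults to USD 13,790/QALY (one GDP per capita under the same guidance).

**Renormalization.** Published probability tables round entries
independently, so rows can sum to 0.99–1.01. Every stage vector and matrix
row is divided by its sum at construction; a deviation beyond 0.02 warns
and beyond 0.05 errors (defaults chosen so that printed-rounding drift
passes silently but data errors do not). `load_fixtures()` tightens the
warning threshold to 0.005 so every adjustment to the packaged tables is
visible in the log. Post-normalization stochasticity is checked to 1e-9.

## Transition estimation from panel data

`fit_transitions()` estimates P<sub>t</sub> by maximum-likelihood
multinomial row proportions of observed year-(t−1) → year-t stage pairs.
Three choices deserve note:

- **Gap handling.** Only consecutive observed pairs are counted; a patient
  seen at years 0 and 2 contributes nothing. The alternative —
  interpolating or fitting a latent-path model — would import assumptions
  the data cannot check at this sample size; skipping is unbiased under
  visits missing at random.
- **Sparse rows.** An optional Laplace pseudo-count (default 0) is offered
  for small panels. A row with no observations and no smoothing becomes an
  identity row ("stay in stage") with a warning: it keeps the schedule
  usable and is the natural no-information default for a process dominated
  by stability.
- **Carry-forward.** Estimation stops at `max_year` (default 3, matching
  follow-up length in the reference cohort); later cycles reuse that
  matrix through the schedule's lookup rather than by copying, so the
  assumption is visible in the object.

The baseline distribution is the stage frequency of year-0 CD4 counts,
restricted to ART-naïve patients when the panel flags them, because CD4
trajectories differ systematically between naïve and experienced patients.

## Costing

Per-stage annual costs enter either as direct totals (initial and
incremental, in USD) or are built from a resource-use table via the cost
equation Σ UC×F×P — unit cost × annual frequency of use × proportion of
users — per stage and phase of care. Amounts priced in MXN are converted
at a configurable rate (default 18.22 pesos/USD, the 2024 average).
Internally costs are double-precision floats; file I/O rounds money to 2
decimals and probabilities to 4, and the round-trip is exact at that
precision. Discounting lives in the Markov engine only, so there is a
single source of truth for time.

`drug_residual_items()` splits given stage totals into one ART-drug line
item (monthly unit cost, 12 dispensations/year, all stages) plus per-stage
residual items. This supports drug-price sensitivity analysis when only
stage totals are published; the residual is an accounting construct, not a
costed resource list.

## Sensitivity analysis

**Probabilistic (PSA).** `run_psa()` re-evaluates the model under joint
perturbation of *all* inputs: every unit cost (or schedule cell), utility,
baseline entry and transition entry is multiplied by an independent draw
from Uniform(1−v, 1+v), v = 0.07 by default. No distributional family was
given for this class of variation, so the uniform band is used — it is the
minimal-assumption reading of "a variation of 7 %" — and the family is an
explicit enumeration in the code should a future version add others.
Utilities are clamped to [0, 1]; the baseline vector and each matrix row
are renormalized after perturbation, which is the simplest construction
that keeps every draw a valid probability structure (perturbing in logit
space would preserve independence of cells but has no support in the
source description). Utility variation defaults to the same ±7 % but
accepts explicit per-stage (low, high) ranges, since utility uncertainty
is usually taken from the literature rather than a blanket percentage.
With a fixed seed the full result is bit-reproducible.

**One-way (tornado).** `tornado()` moves one named scalar at a time to
(1−v)× and (1+v)× its base value — renormalizing any touched probability
structure — and ranks parameters by the largest percent deviation of total
discounted cost from base. Impact is expressed as a percentage of
base-case cost because that is how such analyses are conventionally
reported. A parameter that scales the whole cost schedule has impact
exactly v, which the tests use as an identity check.

## The microsimulation cross-check

`simulate()` on a fitted model runs an individual-level microsimulation of
the same decision problem: each of n individuals draws a baseline stage
and an annual stage path by categorical sampling and accrues discounted
costs and QALYs under the identical convention. The mean converges to the
deterministic trace totals at rate 1/√n, giving an independent oracle for
the matrix algebra; the test suite compares the two routes at n = 200,000
within three standard errors.

## The synthetic cohort generator

`simulate_panel()` emulates the clinical extract the analysis was built
on: 237 ART-naïve patients followed annually for five years, baseline
stage distribution (0.39, 0.22, 0.16, 0.23), stage paths driven by the
packaged year-specific matrices, 95.4 % of visits virally undetectable
(<50 copies/mL), and an adherence index drawn once per patient from
N(89.97, 11.98²) hard-truncated to [0, 100]. Within a stage the CD4 count
is uniform over the stage's bin (the top bin capped at 1500 cells/μL):
only stage occupancy matters to every consumer in the package, so the
least-assumption within-bin law suffices. Ages (normal around the mid-30s,
truncated to 18–80) and gender (≈89 % male) mirror the published cohort
descriptives and exist only for the descriptive-summary utilities.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: visits are exactly annual (no irregular spacing —
gaps are injected separately by `degrade_panel()`), CD4 counts have no
within-person autocorrelation beyond the stage path, no measurement error,
viral load is independent of stage and adherence, and there is no
informative dropout. Truncation (not rejection) is used for the adherence
draws to keep the draw count deterministic; the resulting distribution is
a censored normal, whose mean is lower than the nominal 89.97 by about
1.3 points — the tests compare the sample mean against that censored-normal
value analytically, not against the nominal mean.

## Degenerate inputs and numerical choices

- Stochasticity tolerance 1e-9 after normalization; renormalization
  warn/error bands 0.02/0.05 (0.005 warn on fixture load).
- Zero total QALYs make the cost-per-QALY ratio undefined: `summary()`
  errors rather than returning infinity.
- A zero-cost schedule yields ratio 0 and is (vacuously) below any WTP.
- `sample_size_proportion()` rounds up (a sample size is a count), and
  degenerate proportions 0/1 return 0 with a warning.
- The viral-load dichotomy places the boundary value 50 copies/mL in
  "unsuppressed", so the two categories are exhaustive; the adherence
  threshold 95 is inclusive ("≥95 adherent").
- All randomness (generator, microsimulation, PSA) flows through R's seeded
  RNG; every function with a stochastic step takes a `seed` argument, and
  `run_pipeline()` records the seed in its manifest.

## Recorded discrepancies

Two published headline figures are close to, but not exactly, what the
renormalized printed inputs produce, and the package reports the computed
value in both cases rather than forcing agreement. First, the share of the
cohort in `≥500` at year five computes to ≈0.68 on the packaged matrices
(the reference text says "more than 70 %"); the difference plausibly
reflects unrounded source matrices or a different evaluation point.
Second, compounding the year-0 clinic budget at 12.1 % for five years
gives ≈USD 64.9 M against a published ≈USD 64.75 M; the compounding base
there is unstated.

## Problem sizes used by the test suite

The packaged tests run the base case exactly, the PSA at 10,000
iterations, the microsimulation cross-check at 200,000 individuals, and
parameter recovery on synthetic panels of 500–50,000 patients — sizes at
which the binomial sampling error of the sparsest transition row (origin
`<200` in year 3, whose occupancy has fallen to a few percent) is still
the visible limit on agreement. These sizes are the package's own test
design; all are generated in code at run time.

## Limitations

The model is non-comparative (cost-utility of care as delivered, not an
ICER against an alternative), has no death state or lifetime horizon, no
half-cycle correction variants, no opportunistic-infection or societal
costs, and no covariate-adjusted or continuous-time transition hazards.
The line-item costing mode implements the stated cost equation but cannot
be validated against the original resource workbook, which was not
published; the packaged fixtures therefore use the published stage totals
directly.
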