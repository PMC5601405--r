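---
title: "A two-stage Markov cost-utility model of long-acting G-CSF prophylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage Markov cost-utility model of long-acting G-CSF prophylaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsfcea)
```

## The decision problem

Myelosuppressive chemotherapy depletes neutrophils. Severe neutropenia
(SN, absolute neutrophil count below 0.5 × 10⁹/L) exposes patients to
febrile neutropenia (FN), infection, chemotherapy dose delays and, through
a reduced relative dose intensity (RDI), to poorer long-term survival.
Long-acting granulocyte colony-stimulating factors (G-CSFs) given once
per cycle blunt this cascade. `gcsfcea` implements a cost-utility
comparison of two long-acting G-CSFs — lipegfilgrastim versus
pegfilgrastim — as primary prophylaxis in women with stage II–IV breast
cancer receiving four 21-day chemotherapy cycles, from the perspective of
a third-party payer over a lifetime horizon, in 2015 euro.

Two linked Markov cohort models carry the analysis:

1. **On-chemotherapy model** (21-day cycles, four cycles): tracks SN, FN
   (inpatient/outpatient), infection, chemotherapy delay and
   cause-specific death, accruing costs and quality-adjusted life-years
   (QALYs).
2. **Post-chemotherapy model** (annual cycles to age 100): propagates the
   surviving cohort, stratified by RDI, under combined all-cause and
   stage-mixed breast-cancer mortality. A survival hazard ratio of 1.32
   penalises the RDI < 85% stratum for the first five years; survivors of
   five years are considered cured and face general-population mortality
   only.

Costs are discounted at 3% per year and QALYs at 1.5%; life-years are
reported undiscounted. Both cohorts start as 1,000 women aged 59 with a
stage mix of 38.6% / 47.5% / 13.9% (II / III / IV). Because all costs
accrue during chemotherapy (post-chemotherapy costs are zero by
assumption), the cost comparison is driven entirely by model 1, while the
QALY/life-year comparison is driven mostly by model 2.

## The within-cycle event cascade

The published model structure figure does not pin down every branch, so
the cascade is a design decision of this package, fixed as follows and
validated against the published base-case results (incremental cost −363
euro; this package computes ≈ −359 with identical inputs):

* Each cycle, the cohort mass still on chemotherapy faces the per-arm,
  per-cycle **SN risk**.
* The SN mass splits **exclusively**: first FN-if-SN, then
  infection-if-SN among the non-FN remainder. The two risks are printed
  as identical values and share a single derivation (a gamma distribution
  fitted to the trial's neutrophil counts, mapped to infection risk
  through the granulocyte–infection correlation, with FN conservatively
  set equal to infection), so treating them as competing branches of the
  same mass avoids double-counting a single clinical event.
* The non-SN mass faces the **base FN risk**, apportioned to cycle 1 by
  the linear split `p1 (1 + 3 × 0.213) = 0.032` and scaled in the
  lipegfilgrastim arm by the odds ratio 0.981 (odds scale) or relative
  risk 0.34 (probability scale), per the configured FN risk source.
  Patients with an FN history carry 9.089 times the base risk (capped at
  one). The **infection-if-FN** risk (0.300) applies to this pathway
  only: the SN-derived FN mass already carries the identically derived
  infection-if-SN risk.
* All FN splits 0.800 inpatient / 0.200 outpatient.
* From cycle 2 on, SN and infection patients face the per-cycle **delay**
  risks (direct published inputs; the published Bayes recipe with its
  stated inputs yields an overall ≈ 0.57 and cannot reproduce the
  printed per-cycle values, so the Bayes operation is provided for
  re-derivation experiments but not used in the cascade).
* **Deaths** strike at cycle end with cause-specific risks (FN 0.036,
  SN 0.0005, infection 0.036, delay 0.001), the delay risk compounding
  multiplicatively with the event risk for delayed patients.
* Events are tunnel episodes: all survivors return to the chemotherapy
  state with an updated history stratum (FN history, SN history, naive).
  The 21-day cycle exceeds every episode duration, so no event persists
  across cycles.

Utilities are time-weighted within the cycle: an FN inpatient episode
spends the 6-day length of stay at utility 0.330, FN outpatient 7 days at
0.380, infection 5 days at 0.330, SN 7 days at 0.420, the remainder of
the 21 days at the on-chemotherapy utility 0.700; delayed patients trade
7 days of chemotherapy time for chemotherapy utility × 0.500. Episode
durations beyond the published length of stay are package defaults,
configurable in `config$durations`. Death is applied at cycle end, so
dying patients accrue their final cycle. No half-cycle correction is
applied anywhere (the source analysis is silent on it, and Excel-style
annual-boundary discounting reproduces its arithmetic: all four
chemotherapy cycles fall in year 0 and are undiscounted; post-model year
*t* is discounted by `(1 + r)^-t`).

Infection episodes are costed at the published per-day amounts times
`infection_days` (default 1, so the per-day figures act as per-episode
costs; configurable up to the 5-day antibiotic course). SN management and
chemotherapy delay carry zero cost, as published. A configurable
`costs.delay` slot exists to explore cost attributions to avoided delay.

## Exit stratification and the post-chemotherapy model

At chemotherapy exit the surviving mass is classified by neutropenic
history (FN history / SN-only history / naive) and age band, and each
stratum receives its published risk of RDI < 85% (0.044–0.162; these six
values are direct inputs — they are not derivable from the published
ingredient parameters). The whole base-case cohort exits below 65
(age 59); the price-threshold analysis overrides the starting age per
band.

In post-chemotherapy years 1–5 each stratum's annual death probability
combines all-cause mortality `q_ac` and stage-mixed breast-cancer
mortality `q_bc` as independent competing risks,
`1 − (1 − q_ac)(1 − q_bc)`, with the breast-cancer component raised to
the hazard ratio 1.32 on the cumulative-hazard scale
(`1 − (1 − q_bc)^1.32`) for the RDI < 85% stratum. The hazard ratio
applies to the breast-cancer component only — it is tied to
cancer-related outcomes of reduced dose intensity, not to background
mortality. After year 5, survivors are cured: all-cause mortality only.
Survivor utilities are 0.860 (years 1–5) and 0.960 thereafter. Survivors
at the end of each year accrue that year.

## Synthetic mortality inputs

The original analysis drew breast-cancer mortality by stage from a
national cancer registry and all-cause mortality from national life
tables; neither dataset is publicly deposited. The package therefore
ships a synthetic generator, and makes no claim of matching the original
data — which is also why the published absolute QALY/life-year totals
(13.977 / 13.925 QALYs) are not reproducible by construction, while the
cost side, which needs no mortality input, is:

* `generate_life_table()`: Gompertz form `q(x) = min(1, a e^{bx})`,
  closed (`q = 1`) at age 100. Defaults `a = 1.296e-5`, `b = 0.10` were
  calibrated once with `calibrate_gompertz()` so that a 59-year-old has a
  residual life expectancy of 26 years — plausible for women of that age
  in a western European population (implying, e.g., q(59) ≈ 0.005,
  q(80) ≈ 0.039).
* `generate_bc_mortality()`: year-1 probabilities 0.02 / 0.06 / 0.25 for
  stages II / III / IV decaying geometrically by 0.8 per year over five
  years, i.e. roughly 93% / 82% / 42% five-year cause-specific survival —
  realistic stage gradients for breast cancer. The stage ordering
  IV ≥ III ≥ II is enforced for every year.

What passing tests show, and do not show: the synthetic tables exercise
every structural property of the lifetime model (monotonicity,
conservation, closed-form limits, dominance direction), but absolute
QALY/life-year levels depend on the mortality level chosen and should
not be read as estimates for any real population.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves to the bounds of the 95%
interval of its assigned distribution, or ±30% of the base value where
no distribution is published (the per-cycle FN-if-SN and delay risks,
the delay death risk, cohort age, stage shares), all else held at base;
the full two-model pipeline is re-run at each bound. Entries are ranked
by the spread in incremental cost; re-sort by `spread_qalys` for the
QALY panel.

**Probabilistic (PSA).** 5,000 joint draws by default. Sampling design:

* Parameters printed as one row per arm (“lipegfilgrastim vs.
  pegfilgrastim”: the per-cycle SN risks, the chemotherapy/G-CSF cycle
  cost, the infection per-day costs) are drawn **independently per
  arm**, each from its own printed distribution. This is the package's
  reading of the published table — each arm's row is its own
  parameter — and it is what makes the incremental-cost distribution
  wide enough that the probability of cost-saving lands near the
  published 57% despite a −359 euro deterministic increment: with the
  identical per-arm gamma cycle-cost distributions (sd ≈ 315 euro per
  cycle, four doses) the incremental cost has a standard deviation near
  1,800 euro. Sharing one draw across arms would cancel essentially all
  cost noise and push the probability of cost-saving above 90%,
  inconsistent with the published probabilistic results.
* Single-row parameters (baseline FN risk, ratio estimates, event and
  death risks, hospitalisation share, utilities, ward cost, length of
  stay, outpatient cost) are shared between arms — their uncertainty
  cancels in the increment, as it should for common parameters.
* The FN inpatient episode cost scales multiplicatively with the
  sampled ward cost and length of stay; the infection utility follows
  the FN inpatient utility (published as “same as”); the six RDI
  stratum risks scale with the ratios of their sampled ingredients
  (baseline RDI risks, the age relative risk, the FN-history odds
  ratio), so the base draw reproduces the printed values exactly.
* The per-cycle FN-if-SN / infection-if-SN risks stay at their point
  estimates in the PSA: the published distribution for those rows
  describes the neutrophil count, not the risk, and no published
  granulocyte-to-risk mapping exists to transform draws (the
  `anc_derived_event_risk()` operation accepts a user-supplied mapping
  for exactly such experiments).
* Three published beta rows contradict their point estimates (death if
  FN: mean 0.007 vs 0.036; death if SN: mean 0.070 vs 0.0005; FN
  outpatient cost: a beta with mean ≈ 1 for a 44 euro cost). The
  default samples them verbatim, faithful to the published table;
  `base_case_config(refit_to_mean = TRUE)` reseats the first two on
  their point estimates preserving alpha + beta. The third cannot be
  refitted (44 lies outside beta support) and is left verbatim — its
  weight in results is negligible.
* Out-of-range draws are clipped (probabilities to [0, 1], costs to
  ≥ 0) and clip events are counted in the result, not resampled.
* One master seed expands into per-draw substream seeds; identical
  seeds reproduce draws bit-identically.

**Cost-effectiveness acceptability.** `ceac()` reports, per
willingness-to-pay (WTP) value, the share of draws with positive net
monetary benefit; at WTP 0 this equals the probability of cost-saving by
definition.

**Price threshold.** `price_threshold()` re-runs the deterministic model
over a grid of lipegfilgrastim prices (default 1,000–2,500 euro by 50)
for each cancer stage and age band (35–45, …, 75+, represented by ages
40–80), moving the chemotherapy-cycle cost euro for euro with the drug
price, and records the incremental net monetary benefit at WTP 30,000
euro per QALY. Because the price enters linearly (one dose per cycle
while alive), each cell's zero-crossing has the closed form
`price + NMB(price) / doses`; the grid threshold is checked against this
closed form in the tests as two independent routes to the same number.

## Numerical choices and degenerate inputs

* Occupancy is carried in exact expectation (no microsimulation); mass
  conservation holds to 1e-9 at every cycle and year and is tested
  against an independent path-enumeration oracle on randomised
  configurations.
* Probabilities derived by ratio adjustments are capped at [0, 1]
  (`apply_relative_risk`, the FN-history multiplier); the odds-ratio
  transform is closed on [0, 1) and rejects p = 1.
* An overall FN risk of zero short-circuits the apportionment to zero
  per-cycle risks.
* A life table must cover every age from the starting age to the
  horizon; gaps are an error, not an extrapolation.
* Equal arm inputs produce exactly zero increments (identical floating
  point arithmetic per arm), which the tests assert bitwise.

## Problem sizes

The shipped analyses are sized for an interactive desk run: the
deterministic pipeline is a 4-cycle plus 41-year cohort recursion
(milliseconds); the default PSA uses 5,000 draws (about a minute); the
tornado covers ~50 parameters × 2 bounds; the threshold grid is
3 stages × 5 age bands × 31 prices. The test suite uses reduced draw
counts except where a published probabilistic quantity is checked.

## Known limitations

* The cascade order within a cycle is a reconstruction; alternative
  orderings (e.g. independent rather than exclusive SN branches) change
  arm totals by a few percent.
* Relapse after dose delay, societal-perspective costs, and
  dose-reduction states distinct from delay are out of scope, as in the
  source analysis.
* The published attribution of 10% of cost savings to avoided
  chemotherapy delay has no cost mechanism under the stated zero delay
  cost; the package reproduces the zero-cost reading and leaves
  `costs.delay` configurable.
* Absolute QALY/life-year levels depend on the synthetic mortality
  calibration (see above) and are not estimates of the original
  cohort's values.
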