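---
title: "Methods: the AI-aided LVO detection cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the AI-aided LVO detection cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvohta)
```

## Model structure and assumptions

The package evaluates two strategies for a yearly UK cohort of suspected
ischemic stroke patients receiving CT angiography: usual care, and usual
care plus an AI detection aid that recovers a fraction of the large vessel
occlusions (LVO) the readers would otherwise miss. The comparison has two
stages.

**Acute phase (< 90 days).** A decision tree partitions the cohort by LVO
status (`p_lvo = 0.306`), detection (miss rate `p_missed = 0.06` under
usual care, reduced by `reduction = 0.50` with AI), and thrombectomy
eligibility (`p_eligible = 0.438`). Only detected, eligible LVO patients
receive intra-arterial thrombectomy (IAT); their 90-day modified Rankin
Scale (mRS) outcomes follow a pooled-trial distribution with IAT, all other
LVO patients the distribution without IAT. Two simplifications are built
in, both of which the tree's structure makes harmless: missed-but-eligible
and detected-but-ineligible patients are outcome-identical (neither gets
IAT), and eligibility is independent of detection — so every incremental
quantity is driven by the single mass
`Δf = p_lvo · p_eligible · p_missed · reduction` of recovered eligible
misses. This is also why, at a zero AI fee, the scenario grid depends on
`p_missed` and `reduction` only through their product, and why the
per-analysis fee enters the incremental cost with slope exactly one (the
software screens *every* scanned patient, not only positives). Both
identities are asserted by the test suite.

**Lifetime phase (> 90 days).** The cohort's 90-day mRS distribution seeds
a Markov model over states mRS 0–5 plus death, run for 70 yearly cycles
from age 66. Each cycle applies, in order: general-population mortality
`qx(age)` from a life table; then, among survivors, a recurrent stroke with
probability 2.84%/yr whose new state is drawn from the no-IAT distribution
under a no-improvement constraint; everyone else remains in place. Costs
accrue at end of cycle with discount factor `1.04^(−t)`, utilities with
`1.015^(−t)`.

## Parameters

All defaults are returned by `model_params()` and shipped as
`inst/extdata/config/base_case.yaml`. The ones that matter most:

| parameter | default | units / meaning |
|---|---|---|
| `p_lvo`, `p_eligible` | 0.306, 0.438 | cohort composition (fractions) |
| `p_missed`, `reduction` | 0.06, 0.50 | detection model (fractions) |
| `ai_per_analysis` | 40 | USD per scanned patient, AI arm |
| `tx_iat`, `tx_no_iat` | 11,728 / 1,004 | blended average treatment cost, USD |
| `acute_by_state` | 4,350 … 4,603 | USD per mRS state 0–6, first 90 days |
| `longterm_by_state` | 3,936 … 41,621 | USD per mRS state 0–5 per year |
| `utility_by_state` | 0.95 … 0.11 | QALY weight per mRS state 0–5; death 0 |
| `discount_costs`, `discount_utilities` | 0.04, 0.015 | annual rates |
| `cycles`, `age0`, `cohort_n` | 70, 66, 71,840 | horizon and cohort |
| `wtp_per_qaly` | 25,662 | USD per QALY (£20,000 at the 2019 rate) |

`wtp_per_qaly` is kept at the published dollar figure rather than the
recomputed 20,000 × 1.283 = 25,660; the two-dollar difference is below the
model's reporting precision and fidelity to the published reference value
was preferred. `convert_currency()` exists for users who want their own
rate.

Costs are stored as final 2019 USD; no inflation or currency pipeline is
applied to them (that conversion happened upstream of the published
figures, and re-doing it here would double-convert).

## Design choices where the design was open

*Acute utility accrual.* How much utility the 90-day state contributes
within the acute phase is not a settled convention. The default accrues
`acute_year_fraction = 90/365.25` of a year at the 90-day state's utility,
undiscounted; setting it to 0 drops acute QALYs entirely. Under the
default, the acute incremental QALY is ≈ 0.0002, against a published
rounding-level 0.0001 — the choice is exposed rather than hidden because
no value reproduces a rounded figure unambiguously.

*Non-LVO patients.* Their outcomes cancel exactly in every incremental
result (the branch is identical across strategies — a property the tests
assert), but they set the denominators of percent-of-usual-care figures.
The default profile `healthy` (mRS 0 utility, no stroke costs, background
mortality only, no recurrence) is the interpretation that best matches the
published absolute totals; `non_iat` and `custom` profiles are available.

*Recurrence mechanics.* The source model states only that recurrent-stroke
outcomes follow the no-IAT distribution and that worsening is possible.
The default rule `clamp_max` draws from the no-IAT distribution and clamps
to `max(current, draw)`; `truncate_renormalize` restricts the draw to
states at or above the current one (death included) and renormalizes. Both
conserve probability and never improve a state; the default honors the
no-IAT distribution's literal shape more closely for mildly disabled
patients.

*Within-cycle ordering.* Mortality is applied before recurrence. At the
magnitudes involved (qx of 1–10%, recurrence 2.84%) the ordering shifts
results by well under 0.1%, but it must be fixed for the cohort engine and
the microsimulation to be provably equivalent.

*Half-cycle correction.* None is applied: cycle 1 is a full year starting
at day 90, with end-of-cycle accrual and discount exponent `t`. This is
the simplest convention consistent with the published 70-cycle design, and
the closed-form annuity tests pin it down exactly.

*Recurrence and acute costs.* By default a recurrent stroke does not
re-trigger acute-phase or treatment costs (the source is silent);
`recurrence_acute_costs = TRUE` adds the destination state's acute cost in
the recurrence cycle, discounted like the cycle's long-term costs.

*False positives.* AI false positives are assumed neutralized by the
reader; the only modelled channel is a linear reading-time cost hook
(`fp_rate_points × fp_cost_per_point`, default 0) applied in the AI arm.

## Mortality input and the synthetic life table

The model needs general-population annual death probabilities by age. Two
sources are provided:

1. `gompertz_life_table(a, b, c, max_age)` generates
   `qx = min(1, c + a·e^(b·age))`. The defaults (`a = 3.5e-5`,
   `b = 0.094`, `c = 4e-4`) give a mortality-doubling time of ~7.4 years —
   a realistic adult senescence slope — and are intended for property
   testing and self-contained runs, not as a calibrated national table.
2. The bundled fixture `inst/extdata/life_table_synthetic_uk.csv`,
   assembled by `scripts/make_fixture_life_table.R` from rounded UK-like
   anchor values (log-linearly interpolated across ages). It is
   **synthetic**: a deliberately simple approximation of a recent UK
   national life table, adequate for reproduction to within the tolerances
   the tests use, not a copy of any published table.

Lookups beyond the last tabulated age plateau at the final `qx`, so a
66-year-old cohort run for 70 cycles (to age 136) is always defined;
virtually all mass is absorbed long before the plateau matters. The tables
are unisex and carry no stroke-excess mortality — survivors die at
general-population rates, with recurrence the only stroke-specific hazard,
matching the source model's stated structure. Consequences: lifetime
results reproduce published values only to tolerance (the exact life-table
vintage is unknown), and they respond directly to whatever table the user
supplies.

## The parameter perturbation generator

`random_params(seed, jitter)` multiplies each scalar by an independent
uniform factor in `[1 − jitter, 1 + jitter]`, clamps probabilities and
rates to their ranges, perturbs the mRS distributions entrywise and
renormalizes. Perturbed utilities are re-sorted non-increasing before
validation: independent jitter can otherwise invert adjacent utilities
(0.95 vs 0.93) and produce a parameter set the validator rightly rejects;
sorting preserves the marginal perturbation while keeping every generated
set valid. The generator emulates parameter uncertainty only — it does not
emulate sampling noise in the trial-based outcome distributions, cohort
heterogeneity, or correlated parameter errors — so passing property tests
demonstrate structural invariants (conservation, dominance, linearity),
not calibration to real-world variability.

## Numerical choices

- mRS distributions renormalize inputs whose sum is within 0.5% of 1
  (printed rounded percentages must load) and reject anything further off.
- All internal arithmetic is full double precision; reports round dollars
  to the nearest integer and QALYs to four decimals.
- The cohort engine is deterministic; the microsimulation and the
  parameter generator take explicit seeds and restore the caller's RNG
  state.
- Degenerate inputs are defined, not special-cased: `p_lvo = 0` gives a
  pure non-LVO cohort, `reduction = 0` makes the strategies identical up
  to the AI fee, an all-death start accrues nothing.

## Verification

The test suite checks the engine against independent closed forms and a
second implementation: zero-mortality/zero-recurrence runs must match the
discounted-annuity formulas to 1e-9 relative; the cohort engine must agree
with the seeded per-patient microsimulation within 3 Monte-Carlo standard
errors at 200,000 patients; conservation and absorbing-death monotonicity
hold across 1,000 random parameter sets; and the structural identities
above hold exactly. Problem sizes (1,000 draws, 200,000 simulated
patients, 70-cycle horizons) were chosen so the full suite documents the
model thoroughly while running in seconds. Base-case reproduction checks
run against the bundled synthetic life table at the tolerances stated in
the tests; they are sensitive to the mortality input by design.

## Known limitations

- No time-to-treatment benefit is modelled — only diagnostic accuracy.
- No probabilistic sensitivity analysis or acceptability curves; the
  one-way tornado (defaults: ±20% on costs, probabilities and rates, ±10
  years on starting age) is the uncertainty machinery provided.
- No tunnel states, time-varying recurrence risk, or post-recurrence
  treatment pathways; no sex- or region-stratified mortality.
- Alternative comparator strategies (CT perfusion, extra reader training,
  on-call neuroradiology) are out of scope.
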