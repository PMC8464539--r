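# lvohta

Early health technology assessment (HTA) of AI-aided detection of
intracranial **large vessel occlusions (LVO)** on CT angiography in
suspected ischemic stroke, from a UK societal perspective.

Commercial AI tools claim to reduce the number of LVOs missed by the
radiologist on duty. Whether that is worth paying for — per analysis, for
every suspected-stroke patient scanned — is an economic question: a
recovered miss buys one extra chance at intra-arterial thrombectomy (IAT)
for an eligible patient, which shifts the 90-day modified Rankin Scale
(mRS) outcome distribution toward independence and changes lifetime costs
and quality-adjusted life years (QALYs). `lvohta` implements the full
decision model for analysts who want to reproduce, stress or re-parameterize
that assessment.

## The model

**Acute phase (first 90 days): a decision tree.** A cohort of suspected
ischemic stroke patients receives CTA; a fraction `p_lvo` has an LVO, of
whom `p_eligible` are IAT-eligible. Usual care detects a fraction
`1 − p_missed` of LVOs; the AI-aided strategy detects
`1 − p_missed·(1 − reduction)`, at a fee per analysis applied to every
scanned patient. Only detected, eligible LVO patients receive IAT. Treated
and untreated LVO patients draw their 90-day mRS state from pooled
trial-based outcome distributions (with and without IAT); acute per-state
costs and treatment costs accrue undiscounted.

**Lifetime phase: a Markov cohort model.** The 90-day mRS distribution is
propagated through 70 yearly cycles. Each cycle, patients die at the
general-population probability `qx(age)` from a life table, survivors
suffer a recurrent stroke with probability 2.84%/yr (redrawing their state
from the no-IAT distribution, never improving), and the rest stay put.
Long-term per-state costs are discounted at 4%/yr and state utilities at
1.5%/yr:

    IC = Σ_t Σ_s occupancy_t(s)·cost(s)·(1.04)^(−t)   (AI minus usual care)
    IE = Σ_t Σ_s occupancy_t(s)·u(s)·(1.015)^(−t)
    NMB = λ·IE − IC,  λ = $25,662/QALY (£20,000)

A strategy that saves money (`IC ≤ 0`) while gaining QALYs (`IE ≥ 0`) is
*dominant*; the **threshold (headroom) price** is the per-analysis fee at
which `IC = 0`. A seeded per-patient microsimulation implements the same
rules as an independent cross-check of the cohort engine.

Background mortality comes from a CSV life table (`age,qx`). The package
bundles a **synthetic** UK-like table
(`inst/extdata/life_table_synthetic_uk.csv`) and a Gompertz–Makeham
generator (`gompertz_life_table()`) for fully self-contained runs.

## Worked example

```r
library(lvohta)
params <- model_params()   # published base case: 6% missed, 50% reduction, $40/analysis
mortality <- read_life_table(system.file("extdata",
    "life_table_synthetic_uk.csv", package = "lvohta"))
compare_strategies(params, mortality)
```

```
AI-aided vs usual care, per suspected-stroke patient:
  incremental cost  $-134  (acute $62, rest of life $-196)
  incremental QALYs +0.0091 (acute +0.0002, rest of life +0.0089)
  population (n = 71840): cost $-9656205, QALYs 650.9
  NMB $367/patient at $25,662/QALY; AI strategy dominant
```

Read: the AI arm *costs* $62 more per patient in the acute phase (more —
and more expensive — thrombectomies, plus the $40 fee) but saves $196 over
the remaining lifetime because better 90-day outcomes are far cheaper to
live with, for a net saving of $134 and a gain of 0.0091 QALYs per
suspected-stroke patient; scaled to the yearly UK cohort of 71,840 that is
a $9.7M saving and ~651 QALYs, and the strategy is dominant. Exact lifetime
figures depend on the life-table vintage supplied.

Scenario machinery: `scenario_grid()` (miss rate × AI performance at zero
fee, i.e. headroom per cell), `price_performance_grid()`,
`threshold_price()`, `one_way_sensitivity()` (tornado), and
`microsim_oracle()`. A command-line front end with CSV/manifest output
ships at `inst/cli/lvohta.R`:

```sh
Rscript inst/cli/lvohta.R make-lifetable --out out
Rscript inst/cli/lvohta.R base --life-table out/life_table.csv --out out
```

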