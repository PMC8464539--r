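Package: lvohta
Title: Early Health Technology Assessment of AI-Aided Large Vessel
    Occlusion Detection in Acute Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cost-effectiveness model comparing standard-of-care detection
    of intracranial large vessel occlusions (LVO) on CT angiography against
    AI-aided detection in suspected ischemic stroke. Couples an acute-phase
    (90-day) decision tree to a lifetime Markov cohort model over modified
    Rankin Scale health states with background mortality, recurrent stroke,
    and discounted costs and quality-adjusted life years. Provides scenario
    and price grids, threshold (headroom) pricing, one-way (tornado)
    sensitivity analysis, population scaling, a seeded microsimulation
    cross-check of the cohort engine, a Gompertz-Makeham synthetic
    life-table generator, and a command-line interface with reproducible
    CSV reports.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
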