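Package: cuaengine
Title: Trial-Based Cost-Utility Analysis with Deterministic and Probabilistic Sensitivity Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Engineering", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A config-driven engine for two-strategy cost-utility analysis from
    the payer perspective: quality-adjusted life year (QALY) accrual, incremental
    cost-effectiveness ratios (ICER) with dominance classification, net monetary
    benefit, one-way (tornado) sensitivity analysis, and seeded Monte-Carlo
    probabilistic sensitivity analysis with method-of-moments beta/gamma
    parameter distributions, cost-effectiveness plane quadrant classification,
    threshold decision rules and acceptability curves. Includes a synthetic
    two-arm trial generator (gamma costs, beta utilities) so every pipeline
    stage is testable without patient-level data, and a command-line interface
    with tabular exports and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
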