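Package: stepscea
Title: Cost-Utility Markov Modelling of Nationwide Physical-Activity Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-cohort Markov cost-utility model for nationwide
    step-challenge style physical-activity interventions. Twelve health states
    (healthy, diabetes and hypertension at three physical-activity levels,
    cardiovascular and stroke complications, death) are propagated over annual
    cycles with half-cycle correction and discounting; the package computes
    incremental QALYs, averted cases and deaths, health-system and societal
    cost reductions and the ICER, and provides probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves, one-way
    deterministic (tornado) sensitivity, threshold (break-even) analysis, a
    physical-activity cost-differentiation scenario, a synthetic parameter
    generator, an individual-level microsimulation oracle and YAML
    configuration I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
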