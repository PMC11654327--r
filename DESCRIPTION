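Package: vescasim
Title: Simulation and Rasch-Based Adjustment of Examiner Scores in
    Distributed OSCEs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates distributed Objective Structured Clinical Exams
    (OSCEs) with known true student performance, links otherwise fully
    nested examiner cohorts through shared video scoring (the VESCA
    linking design), fits a three-facet many-facet Rasch rating-scale
    model by joint maximum likelihood, and measures whether
    severity-adjusted (fair-average) scores land closer to the true
    scores than the raw observed scores. Includes the full Monte-Carlo
    study grids over linking intensity, examiner participation,
    between-school baseline stringency differences, station counts and
    residual error, with pooled error-ratio and accuracy-proportion
    summaries and adjustment-size threshold tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
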