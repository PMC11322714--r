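Package: rdtime
Title: Regression Discontinuity in Time for Person-Day Event Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interrupted health-service utilization analysis with a
    regression discontinuity in time design. Builds per-user, per-day binary
    event panels from transaction logs (or a built-in synthetic cohort
    generator), derives a containment stringency index from ordinal policy
    indicators, fits segmented modified Poisson regressions (log link with
    heteroskedasticity-robust sandwich variance) around a policy cutoff,
    selects the analysis window with an Imbens-Kalyanaraman plug-in bandwidth,
    computes counterfactual recovery times from the fitted discontinuity and
    slope change, and runs bandwidth sensitivity scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    sandwich,
    optparse
Config/testthat/edition: 3
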