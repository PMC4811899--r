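Package: bustdm
Title: Busulfan Therapeutic Drug Monitoring: Curve Fitting, Fit-Quality
    Scoring and Dose Individualization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational back-end for busulfan therapeutic drug monitoring
    (TDM). Fits individual plasma concentration-time profiles to one- or
    two-compartment intravenous-infusion models by weighted nonlinear least
    squares (Levenberg-Marquardt) with curve-stripping initial estimates,
    applies nested model-selection logic with a model-independent
    (non-compartmental) fallback, collapses goodness-of-fit criteria to a
    10-point tachometer score banded green/yellow/red, and simulates doses to
    hit clinician-specified exposure targets (AUC per dose, average
    steady-state concentration, or cumulative course AUC). Includes a seeded
    synthetic-cohort generator with an ODE oracle for validation, profile
    CSV/JSON input with point exclusion, and time-stamped report assembly
    with a duplicate-submission registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
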