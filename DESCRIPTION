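Package: quizpk
Title: External Validation Toolkit for a Quizartinib Population Pharmacokinetic Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating a fixed-parameter population
    pharmacokinetic (popPK) model of quizartinib in plasma. Implements a
    mamillary three-compartment oral-absorption structural model solved in
    closed form, population (PRED) and maximum a posteriori empirical-Bayes
    individual (IPRED) prediction, the standard external-validation metric
    suite (MPE, MdPE, MdAPE, F20, F30, stratified errors, R squared) with
    acceptability gates, normalized prediction distribution errors (NPDE),
    prediction-corrected visual predictive checks (pcVPC), steady-state
    trapezoidal AUC, a synthetic-cohort generator emulating a sparse
    steady-state therapeutic drug monitoring design, and the statistical
    content of LC-MS/MS bioanalytical method validation (weighted calibration
    regression, accuracy/precision batches, LLOQ, carryover, selectivity,
    matrix effect and recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
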