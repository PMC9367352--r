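Package: leukodyn
Title: Tumor-Immune-Chemotherapy Dynamics for Murine Leukemia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the in vivo dynamics of murine A20 leukemia under
    chemotherapy with an ordinary differential equation model coupling
    logistic tumor growth, effector-cell interaction and impulsively dosed
    drug pharmacokinetics. Provides clinical-style dose arithmetic
    (mg/kg to molecule counts, half-life to decay rate), two-point
    exponential growth-rate estimation, equilibrium and stability analysis
    via Jacobian eigenvalues, sensitivity analysis and bisection calibration
    of the drug cytotoxicity rate, combination-therapy prediction, and a
    synthetic flow-cytometry mouse-cohort generator with the matching
    growth-inhibition estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
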