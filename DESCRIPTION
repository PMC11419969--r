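Package: tacropk
Title: Population Pharmacokinetics and Dose Individualization of
    Tacrolimus Under Voriconazole Co-Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic (PopPK) analysis of
    tacrolimus in renal transplant recipients receiving concomitant
    voriconazole. Implements a one-compartment oral model with
    first-order absorption and elimination in closed form, covariate
    scaling of clearance and volume by voriconazole concentration and
    serum creatinine, nonlinear mixed-effects estimation by the Laplace
    approximation, stepwise covariate selection on the objective
    function value, bootstrap and (prediction-corrected) visual
    predictive check model validation, and Monte Carlo simulation of
    day-3 trough concentrations with probability-of-target-attainment
    (PTA) dose recommendation. A synthetic cohort generator with known
    ground truth supports parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
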