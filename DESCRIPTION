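Package: grpkpd
Title: Glucocorticoid Receptor Trafficking Kinetics and Dose-Regimen
    Pharmacodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for a seven-state kinetic model of glucocorticoid
    receptor (GR) trafficking between cytoplasm and nucleus. Provides the
    analytic steady state of the model, its high- and low-concentration
    Michaelis-Menten reductions, stiff time-dependent integration under
    arbitrary free-plasma concentration forcing (including a two-species
    labeled/unlabeled cold-chase variant), linear pharmacokinetic models
    for dexamethasone and methylprednisolone, a nonlinear
    prednisone/prednisolone model with saturable transcortin binding, a
    synthetic diurnal free-cortisol forcing profile, and the glucocorticoid
    transcription quotient (GTQ) for comparing dosing regimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
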