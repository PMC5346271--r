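Package: fishrtk
Title: Physiologically Based Toxicokinetic and Reverse-Dosimetry Models for Teleost Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental physiologically based toxicokinetic (PBTK) models of
    waterborne chemical uptake in teleost fish at three levels of physiological
    fidelity (seven-compartment, six-compartment and one-compartment), together
    with their exact steady-state inversion for exposure reconstruction (reverse
    toxicokinetics), relaxation half-life protocols, log-normal population
    sampling, structural-variant analysis, and the in vitro to in vivo
    extrapolation (IVIVE) comparison statistics that contrast model predictions
    against whole-organism effect thresholds. Includes a synthetic chemical-assay
    generator and a config-driven experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
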