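Package: runtumble
Title: Steady-State Bacterial Taxis from Intracellular Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale model of bacterial navigation in one-dimensional
    chemical and non-chemical gradients. Receptor-cluster activity follows the
    Monod-Wyman-Changeux two-state model with methylation adaptation; motor
    switching follows an ultrasensitive Hill response of the clockwise bias to
    kinase activity. A closed-form steady-state cell distribution couples these
    single-cell dynamics to population profiles for chemotaxis, pH taxis,
    thermotaxis, and mixed chemical/thermal gradients, with an agent-based
    run-and-tumble simulator serving as an independent stochastic check.
    Includes sensitivity analysis (effective population sensitivity),
    preferred-point and tunability analyses for precision sensing, and
    effective-potential diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
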