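Package: pacbs
Title: Convergent Born Series Simulation of Photoacoustic Fields from
    Erythrocyte-Like Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frequency-domain simulation of two-dimensional photoacoustic
    pressure fields generated by optically absorbing circular disks that
    mimic red blood cells. Provides exact analytic solutions for a single
    fluid disk and their linear superposition (the discrete particle
    approach), a preconditioned convergent Born series solver for the
    inhomogeneous Helmholtz equation on a pixel lattice with a sigmoid
    absorbing boundary layer, a Metropolis-Hastings generator of
    non-overlapping blood-smear phantoms, and harnesses for center-line
    field comparisons, frequency sweeps at ring detectors, and ensemble
    statistics over tissue realizations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
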