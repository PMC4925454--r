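Package: tetheravidity
Title: Mean Capture Time and Binding Enhancement for Polymer-Tethered Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic mean time to capture for a ligand held by a Gaussian
    polymer tether near an absorbing receptor sphere, obtained from the
    steady-state advection-diffusion problem in the tether's harmonic
    potential with a reflecting boundary at full extension. Includes two
    independent validation oracles (a backward-equation mean-first-passage
    quadrature and an overdamped Brownian dynamics simulator), the
    three-state free/singly-bound/doubly-bound kinetic model with its
    avidity enhancement factor, and the tether-length dose-response curve
    with nonlinear least-squares fitting and a synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
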