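Package: mtmd
Title: Mass Tensor Molecular Dynamics with Variable Cell Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Molecular dynamics with a position-dependent mass matrix (mass
    tensor molecular dynamics, MTMD) generalized to variable cell shape
    (Parrinello-Rahman, NpH ensemble). Provides a second-order, time-reversible,
    symplectic generalized-leapfrog integrator with implicit stages, mass
    matrices built from a reference Hessian in redundant internal coordinates
    (Wilson B matrix) under a constant-determinant constraint, a diatomic
    mode-resolved mass matrix, simple molecular force fields for nitrogen and
    toy polyatomics, and trajectory analysis tools: mode-filtered vibrational
    power spectra, mass-weighted Hessian frequencies, time-step stability
    scans, radial distribution functions, diffusion-coefficient fits, and a
    polymorph-transition detector.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
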