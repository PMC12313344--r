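Package: smcloop
Title: Coarse-Grained Simulation of SMC-Mediated DNA Loop Extrusion with
    Anisotropic Segment Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulator of a bead-spring DNA polymer on which a
    structural-maintenance-of-chromosomes (SMC) complex such as condensin extrudes a
    loop by repeated geometry-constrained DNA segment capture. The capture region is
    a truncated open spherical sector of aperture gamma (the "grabbing angle") whose
    axis runs from the SMC anchor through its heads; combined with an irreversible,
    ATP-like rebonding move this breaks detailed balance and, for gamma < 360
    degrees, spontaneously rectifies loop growth. The package provides the polymer
    force field (WCA, FENE, Kratky-Porod bending, harmonic SMC springs, dihedral
    torsion variants), an overdamped Langevin integrator with optional slab
    confinement and end tethering, five SMC structural variants, observables for
    loop-trace statistics (RMS extruded length and its scaling exponent, step-size
    distributions, capture success probability, extrusion velocity, grabbing-angle
    sweeps), deterministic test fixtures, configuration files and a small command
    line front end. Analysis functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
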