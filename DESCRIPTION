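Package: cortigrow
Title: Two-Field Finite-Element Simulation of Cortical Folding Driven by
    Proliferating Zones
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates human fetal cortical folding on a two-dimensional
    quarter-annulus brain section by coupling quasi-static finite-growth
    hyperelasticity (multiplicative decomposition, anisotropic density-driven
    growth tensor, neo-Hookean elasticity) to an advection-diffusion-reaction
    model of neuronal cell density with two proliferating zones: the
    ventricular zone (VZ) and the outer subventricular zone (OSVZ), whose
    outer boundary expands by mitotic somal translocation. Provides bilinear
    quadrilateral finite elements with Newton iteration and staggered field
    coupling, morphometric readouts (folding evolution, sulcus depths,
    instability detection, inter-sulcal distances, radial density profiles,
    OSVZ thickness maps), YAML run configurations with experiment presets,
    VTK and CSV output, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
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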