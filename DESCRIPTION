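Package: bactglass
Title: Glassy Dynamics Analysis for Dense Motile Bacterial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based analysis of the glass transition in dense
    two-dimensional suspensions of motile, growing bacteria. Implements
    differential variance analysis (overlap function and chi4 dynamic
    susceptibility), structure-tensor nematic orientation fields with
    orientational correlators and microdomain statistics, static structure
    factors, relaxation-law fitting (stretched exponential, mode-coupling
    power law, Vogel-Fulcher-Tammann), per-cell segmentation and tracking
    with kinematic statistics, and a self-propelled growing-rod simulator
    that renders phase-contrast-like movies with ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    minpack.lm,
    jsonlite,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
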