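Package: trabevalid
Title: Micro-Finite-Element Modelling and Deformed-Morphology Validation of
    Cement-Augmented Trabecular Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds specimen-specific voxel-based micro-finite-element (microFE)
    models of cement-augmented trabecular structures from micro-CT-style image
    stacks and validates them by pixel-wise comparison of the predicted deformed
    morphology against images of the loaded specimen. Includes a synthetic
    open-cell foam phantom generator with a micro-CT imaging emulator, image
    stack input/output (TIFF, NRRD, MetaImage) with block-mean downsampling,
    two-threshold segmentation with connectivity filtering, landmark-based
    boundary-condition estimation, a matrix-free conjugate-gradient linear
    elasticity solver for two-material voxel hexahedral meshes with tied or
    linearized frictionless cement-bone interfaces, and the false-positive /
    false-negative deformed-morphology overlap metric with slice-plan
    extraction and reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    png,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
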