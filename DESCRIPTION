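Package: dirqa
Title: Multiparametric Quality Assurance for Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-phantom toolkit for quantitative quality assurance of
    deformable image registration (DIR) in CT-based radiotherapy workflows.
    Generates synthetic CT volumes of a bending-stick phantom and a
    head-and-neck-like shrinking-mass phantom with analytic ground-truth
    deformations, remaps tissue contrast with a quadratic Hounsfield-unit
    transfer curve, provides a multi-resolution demons-type stand-in DIR with
    box-based local-rigid refinement, and scores registrations with a suite of
    similarity indices (marker distance, sphere centroid distance, maximum
    diameter difference, Dice coefficient, Hausdorff distance) including
    self-registration sensitivity estimation, study protocols, paired Wilcoxon
    signed-rank comparison, and spider-graph reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
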