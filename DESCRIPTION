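Package: dirqa
Title: Quality Assurance Metrics for Deformable Contour Propagation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates the geometric accuracy of automatically propagated
    radiotherapy structure sets against manual ground-truth delineations.
    Implements voxel-mask comparison metrics on anisotropic grids (Dice
    similarity coefficient, mean surface distance, Hausdorff distance),
    population surface-distance projection maps with pixelwise percentiles,
    patient-level aggregation with exact paired Wilcoxon signed-rank tests,
    and volume-ratio accuracy analysis. Ships a fully synthetic pelvic
    cohort generator (parametric organ phantoms, smooth residual
    deformation fields, modality delineation bias, intra-observer noise)
    so that every stage of the pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    readr,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
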