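Package: bodyatlas
Title: Whole-Body MRI Atlas Construction, Unbiasing and Voxel-Based
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds population-averaged whole-body MRI atlases from
    cohorts of 3D volumes: phenotype-driven cohort partitioning by sex
    and body-mass index, median-phenotype reference selection,
    intensity and spatial pre-processing, affine plus diffeomorphic
    B-spline free-form-deformation registration with multi-resolution
    pyramids, atlas averaging with inverse-field unbiasing,
    probabilistic organ and fat label atlases, registration-quality
    metrics (Dice overlap, 95th-percentile Hausdorff distance, folding
    ratio), and voxel-based morphometry with general-linear-model
    z-maps under false-discovery-rate control.  A phantom module
    generates synthetic 3D bodies with known ground-truth deformations
    so every stage can be validated against simulated truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
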