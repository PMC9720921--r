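Package: hii
Title: Hematoma Irregularity Index from CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes the hematoma irregularity index (HII), a
    dimensionless 3D shape statistic comparing the surface-area-equivalent
    and volume-equivalent sphere radii of an intracerebral hemorrhage
    segmented from non-contrast CT. Provides Hounsfield-unit threshold
    segmentation, watertight isosurface reconstruction with physical voxel
    spacing, the hematoma-expansion classification rule, synthetic CT
    phantoms with analytic ground truth, and the accompanying cohort
    statistics (baseline comparison with a normality gate, univariate and
    multivariate logistic regression, ROC analysis with the Youden cutoff,
    Hosmer-Lemeshow calibration, and one-way intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
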