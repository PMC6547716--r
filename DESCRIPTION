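Package: amynet
Title: Distant and Local Amyloid Effects on Brain Metabolism and Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise multimodal regression analysis of amyloid-beta (Abeta)
    PET, FDG PET and gray-matter density images: a per-voxel general linear
    model engine with voxel-level and global predictors, family-wise error
    control by Freedman-Lane max-|t| permutation, cross-modal
    partial-correlation connectivity matrices with seed-to-voxel maps and
    seven-network overlap decomposition, Abeta-by-hypometabolism interaction
    models of longitudinal cognitive decline with nested-model comparison and
    bootstrap stability analysis, and a recursive path (structural equation)
    model with CFI and SRMR fit indices. Includes a synthetic multimodal
    cohort generator with network-structured region covariance for
    calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
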