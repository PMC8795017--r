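Package: labradiomics
Title: Radiomics and Machine Learning Pipeline for Labyrinth MRI Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a radiomics pipeline for
    computer-aided diagnosis of Meniere's disease from conventional
    T2-weighted MRI of the inner-ear labyrinth. Provides a seeded
    multi-center synthetic labyrinth-phantom cohort generator, isotropic
    resampling with cubic-spline interpolation, Z-score normalization and
    fixed-bin-width discretization, a from-scratch 3D radiomic feature
    engine (shape, first-order, and five texture-matrix families on the
    original image and eight stationary Coiflet-1 wavelet sub-bands, 812
    features in total), PCA-based feature reduction with loading-derived
    feature contributions, a multi-layer-perceptron classifier trained
    with Adam and early stopping, and diagnostic evaluation (center-aware
    train/test split, stratified 10-fold cross-validation, sensitivity,
    specificity, predictive values, AUC, F1, MCC with bootstrap CIs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
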