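Package: HiClassify
Title: Hierarchical Top-Down Classification and Taxon Prediction for
    Biomolecular Feature Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Top-down hierarchical classification of biomolecular feature
    matrices (mass-spectral profiles, gene expression tables) along a class
    taxonomy. A discriminant model is trained at every internal node of the
    hierarchy, with the method (SIMPLS partial least squares, maximum margin
    criterion LDA, Fisherfaces PCA-LDA, or linear SVM) chosen per node by
    nested stratified cross-validation, followed by a one-vs-all logistic
    probability layer. Samples are classified by probabilistic descent from
    the root with a probability-difference non-classification rule, and
    unknown terminal classes are predicted at upper taxonomy levels by
    leave-one-class-out evaluation. Includes the accompanying spectral
    preprocessing chain (binning, adaptive histogram denoising, TIC replicate
    selection, Savitzky-Golay peak detection, kernel-density peak matching,
    median-fold-change normalization) and an expression-table preprocessing
    chain, plus synthetic hierarchical-Gaussian and multi-peak spectrum
    generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    graphics,
    utils,
    jsonlite,
    e1071,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mzR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'HiClassify-package.R'
    'utils.R'
    'hierarchy.R'
    'reducers.R'
    'node_model.R'
    'selection_cv.R'
    'io.R'
    'ms_preprocess.R'
    'prediction.R'
    'synthetic.R'
    'table_preprocess.R'
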