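Package: multiPit
Title: Multimodal Optical Image and Raman Analysis of Pituitary Tissue
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-level morpho-molecular classification of pituitary gland and
    adenoma biopsies from co-registered multimodal optical images (OCT, TPEF,
    SHG, MPM) and line-scan Raman microspectroscopy. Provides a synthetic
    multimodal cohort generator; radiomic texture features (first-order, GLCM,
    GLSZM) with cohort-global intensity binning and Pearson redundancy
    reduction; balanced Monte-Carlo cross-validation with R-squared feature
    ranking, Tomek-link cleaning, SMOTE oversampling and a mixed random-forest
    ensemble for gland-versus-adenoma discrimination; Raman preprocessing
    (iterative-polynomial fluorescence baseline removal, Savitzky-Golay
    smoothing, C-H band normalization) with PCA-SVM adenoma subtyping and
    band-ratio biomarkers; the corrected optical redox ratio NADH/(NADH+FAD);
    and a five-axis multiparametric biomarker fingerprint.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    randomForest,
    igraph,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Classification, Spectroscopy, FeatureExtraction, Software
RoxygenNote: 7.3.3
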