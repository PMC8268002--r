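Package: peristas
Title: Intra- and Perinodular CT Radiomics for Predicting Spread Through
    Air Spaces in Lung Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for peritumoral radiomics of lung nodules on
    non-contrast chest CT. Builds millimetre-accurate perinodular shells
    (2-20 mm) and a tumor-lung interface band from a nodule mask by
    thresholding an exact Euclidean distance transform clipped to the lung;
    extracts 851 radiomic features per volume of interest (3D shape,
    first-order intensity, and GLCM/GLRLM/GLSZM/GLDM/NGTDM texture families
    on the original image and on eight wavelet bands); and models spread
    through air spaces (STAS) status with an imbalance-aware pipeline
    (z-score standardisation, Pearson-correlation deduplication, SMOTE,
    recursive feature elimination wrapped around AdaBoost, stratified
    cross-validated probability estimation) evaluated with ROC analysis,
    Youden-index operating points, bootstrap confidence intervals and the
    DeLong test. A synthetic CT phantom generator provides labelled
    cohorts with a plantable perinodular signal so the whole chain is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    rpart,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
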