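Package: seraman
Title: Serum Raman Spectral Metabolomics: Preprocessing, Peak
    Quantification and Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for label-free Raman spectroscopy of
    patient sera in the fingerprint region (600-1800 cm-1). Implements
    spectral preprocessing (replicate-consensus cosmic-ray repair,
    Savitzky-Golay smoothing, iterative modified-polyfit fluorescence
    baseline subtraction, standard-normal-variate normalization),
    ratiometric quantification of a 40-band serum metabolite peak panel
    against the 1448 cm-1 CH-deformation band, and the cross-sample
    statistics used in serum biomarker studies: volcano analysis with
    homoscedastic t-tests, Pearson correlation matrices, univariate
    ROC-AUC with stratified bootstrap confidence intervals, PCA and
    PCA-tSNE embeddings, linear-SVM leave-one-out cross-validation with
    nested cost selection, neoadjuvant-rectal-score responder
    stratification, and a signed -log10(p) rank metric for gene-set
    enrichment exports. A synthetic-cohort generator with a full
    ground-truth record supports recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    tibble,
    dplyr,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    cluster,
    withr,
    kernlab,
    optparse
Config/testthat/edition: 3
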