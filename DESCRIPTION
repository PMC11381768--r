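Package: metabopanel
Title: Metabolite Panel Selection and Targeted Quantification for Plasma
    LC-MS Metabolomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end workflow for support-vector-machine based
    discovery of minimal diagnostic metabolite panels from untargeted
    LC-MS feature tables, and their absolute quantification by stable
    isotope dilution.  Provides pooled-QC signal-drift correction with
    below-detection imputation, per-sample L2 normalization, a linear
    soft-margin SVM with squared-weight feature importance, repeated
    stratified cross-validation with progressive top-N panel curves,
    1/x^2-weighted least-squares calibration with back-calculation
    acceptance rules and LLOQ/LLOD estimation, diagnostic-model
    evaluation (ROC, precision-recall, confusion metrics,
    Benjamini-Hochberg adjustment), metabolite-ratio response-marker
    analysis, and synthetic cohort generators that emulate the
    statistical structure of case-control plasma metabolomics studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    kernlab,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
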