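Package: tfinduce
Title: Transcription-Factor Induction Profiling, Enrichment and Direct-Target Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcription-factor (TF) induction screens in
    embryonic stem cells: control-channel normalization of log-scale expression
    intensities, per-gene batch normalization, per-TF induction profiles
    (logratio, Welch p, Benjamini-Hochberg FDR) with responder calling and PCA,
    correlation of induction signatures against a tissue-expression atlas with
    Fisher-z significance and clustered heatmap ordering, parametric gene-set
    enrichment (PAGE) on expression quartiles, ChIP-seq peak-to-transcript
    annotation with symbol-score/TSS-distance scoring and promoter/enhancer
    classes, and direct-target calling by expected proportion of false
    positives (EPFP) with sliding-window rank-plot validation. A synthetic-data
    module generates all inputs with planted ground truth so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    IRanges,
    S4Vectors,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
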