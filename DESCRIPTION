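Package: agomir
Title: Serum-Fraction microRNA qRT-PCR Analysis for Argonaute-Associated
    Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for qRT-PCR cycle-threshold (Ct) panels of
    circulating microRNAs measured across serum fractions (whole serum,
    exosomes, Ago1/Ago2 immunoprecipitates, blood-cell fractions). Covers
    Ct inversion and reference-subset mean normalization, input-volume
    adjustment of global expression, blood-fraction and Ago1-vs-Ago2
    specificity calls, correlation-distance hierarchical clustering of
    samples, Mann-Whitney differential calling between heart-failure and
    control groups, composite diagnostic scores with empirical ROC/AUC and
    Youden operating points, and a synthetic-cohort generator with planted
    ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
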