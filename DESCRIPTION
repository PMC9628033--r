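Package: methcormap
Title: Cross-Tissue DNA Methylation Correlation Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genome-wide correlation maps of DNA methylation between a
    surrogate tissue and a target tissue profiled in the same individuals
    (e.g. buccal swabs paired with prefrontal cortex). Implements array-style
    quality control, reference-based cell-composition estimation, principal
    component based detection and linear removal of technical and biological
    covariates, per-CpG Spearman rank correlation with Benjamini-Hochberg
    false discovery control, cis methylation quantitative trait locus (mQTL)
    mapping by additive linear models, and chi-squared enrichment analyses of
    mQTL status and genomic-region annotation on spatially decorrelated
    backgrounds. A fully parameterised simulator generates paired-tissue beta
    matrices with planted cross-tissue correlation, cell-mixture and batch
    confounding, and cis genetic effects, together with a machine-readable
    truth table for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    vcfR,
    withr
Config/testthat/edition: 3
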