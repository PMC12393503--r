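Package: toxitemporal
Title: Temporal Expression Reprogramming and Multi-Omic Exposure Signatures
    in Longitudinal Toxicant Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for longitudinal multi-omic toxicant-exposure
    studies in the mouse: classification of gene expression trajectories
    across weaning, young and later adulthood into nine temporal patterns
    and quantification of exposure-induced pattern reprogramming;
    differential calling of expressed genes, accessible regions and
    methylated regions with exposure-specific versus multi-response
    signature decomposition and cross-tissue (target versus surrogate)
    concordance; a PCA-based sex discrepancy score with permutation
    deviation testing and feminization analysis of sex-biased genes;
    chromatin-state switch annotation of differential regions against
    paired segmentations; hypergeometric over-representation analysis;
    and a truth-tracked synthetic cohort generator emulating a two-sex,
    three-age, nine-exposure study design so that every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
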