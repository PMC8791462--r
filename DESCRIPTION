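Package: hervscreen
Title: Discovery of Shared HLA-Presented Epitopes from Cancer-Associated
    Endogenous Retroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying shared CD8+ T cell epitope candidates
    derived from human endogenous retroviruses (HERVs) overexpressed in
    tumors. Provides counts-per-million normalization, a negative-binomial
    Wald test with fold-change shrinkage for tumor versus peritumoral
    comparisons, annotation of cancer-associated HERVs, L1-penalized
    regression against immune phenotype and function signatures to flag
    cytotoxicity-associated HERVs, six-frame open reading frame detection
    with homology filtering against retroviral Gag/Pol proteins, HLA-binding
    screening and epitope sharing analysis, cumulative expression (pi-value)
    scores, survival stratification by HERV-set expression terciles, and
    methylation-probe correlation. A seeded synthetic-data generator emulates
    every input so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    fgsea,
    glmnet,
    methods,
    rtracklayer,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
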