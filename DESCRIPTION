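Package: vmsig
Title: Gene-Signature Derivation, Scoring and Enrichment for Vasculogenic-Mimicry Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving transcription-factor target and tumor-endothelial gene
    signatures from differential-expression tables, scoring them in bulk cohorts
    (per-sample mean Z) and in single cells (rank-based AUC recovery curves), running
    pre-ranked gene set enrichment analysis with a weighted Kolmogorov-Smirnov statistic
    and gene-set-permutation FDR, classifying endothelial-like ("endo-high") tumor cells
    in CellTag-labelled single-cell RNA-seq data, and generating seeded synthetic
    datasets (differential-expression quartets, cohort matrices with planted correlated
    modules, negative-binomial single-cell counts with planted subpopulations) that make
    every stage of the pipeline verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
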