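Package: scMMP
Title: Metabolic Meta-Program Discovery for Single-Cell Tumour Atlases
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A pipeline for dissecting intratumour metabolic heterogeneity
    from multi-sample single-cell RNA-seq cohorts. Covers quality control and
    normalization, lightweight copy-number based malignant-cell
    identification, rank-based (AUCell-style) gene-set scoring, per-sample
    non-negative matrix factorization with robust-program filtering and
    greedy clustering into metabolic meta-programs (MMPs), MMP abundance and
    association statistics, co-occurrence networks, and consensus clustering
    of cell-type-specific pseudo-bulk profiles. Ships a synthetic cohort
    generator that plants known cell types, CNV segments and metabolic gene
    programs so every stage of the pipeline can be tested against a known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
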