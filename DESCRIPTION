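Package: devostate
Title: Developmental-Status-Aware Decomposition of Bulk Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tissue-specific fetal and adult cell-state signature
    matrices from annotated single-cell UMI counts, decomposes bulk RNA-seq
    profiles into relative cell-state fractions with a nu-support-vector
    regression or non-negative least squares mixture solver, and derives a
    per-sample fetalness index quantifying the aggregated fetal cell programs
    in a sample. Downstream statistics include mutual-information gene-set
    enrichment with a permutation null, fetal-centroid nearest-neighbor
    enrichment in principal-component space, Cox and Kaplan-Meier survival
    association, stem-cell-marker correlation shift tests, CRISPR dependency
    enrichment and drug-response correlation. Seeded synthetic-data
    generators provide ground-truth references, mixtures and cohorts so
    every pipeline stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    e1071,
    pracma,
    survival,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, GeneExpression, RNASeq,
    DifferentialExpression, Survival, ImmunoOncology
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'reference.R'
    'deconvolution.R'
    'embedding.R'
    'enrichment.R'
    'clinical.R'
    'simulate.R'
    'cli.R'
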