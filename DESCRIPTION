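Package: microrepop
Title: Identification of CSF1R-Inhibition-Resistant MAC2+ Microglia from
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for characterising the rare, progenitor-like
    MAC2/Lgals3-high microglial subpopulation that survives CSF1R inhibition.
    Covers quality control of 10x-style count matrices, log-normalisation with
    covariate regression, highly-variable-gene selection, PCA and
    shared-nearest-neighbour graph clustering with contaminant-cluster removal,
    two-part hurdle-model differential expression, mean-plus-k-SD marker
    gating with condition frequency tables, developmental-stage gene-signature
    overlap scoring, negative-binomial GLM differential cell abundance, and
    adaptive-threshold immunofluorescence colocalization quantification.
    Includes a synthetic-data generator emulating the three-condition,
    nine-population study design so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    MASS,
    igraph,
    RANN,
    irlba,
    edgeR,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
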