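Package: TILprofiler
Title: Immune Contexture Profiling of Tumor-Infiltrating T Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing immune-checkpoint expression on
    tumor-infiltrating T cells from flow cytometry and single-cell
    RNA-seq with paired TCR sequencing. Implements supervised subset
    gating with per-subset checkpoint positivity and MFI summaries, a
    PhenoGraph-style unsupervised pipeline (auto-logicle transform,
    kNN-Jaccard graph, Louvain communities), a single-cell stage (QC,
    log-normalization, variance-stabilized highly variable gene
    selection, grid-based dimension reduction and clustering, cell-cycle
    scoring, lineage assignment, filtered Wilcoxon differential
    expression), clonotype calling and repertoire metrics from contig
    annotations, and the joint stratification of T cells by TCR
    clonality and checkpoint expression into HC_HE, HC_LE, LC_HE and
    LC_LE compartments. A synthetic-cohort generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster,
    mclust,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    uwot,
    Seurat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
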