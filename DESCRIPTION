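Package: scTME
Title: Multi-Sample Tumor Single-Cell RNA-Seq Microenvironment Analysis
Version: 0.1.0
Authors@R: person("TME", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for multi-sample tumor
    single-cell RNA-seq: gene-count cell filtering, TP10K log-normalization,
    highly-variable-gene selection, PCA, shared-nearest-neighbor modularity
    clustering and Wilcoxon rank-sum differential expression; template-based
    cluster annotation (majority template label with a confidence threshold);
    binned module scores with highest-positive-score classification (cell
    cycle, molecular subtype, outcome); per-sample cellular composition,
    T-cell-infiltration classification and immunohistochemistry correlation;
    and a permutation-null ligand-receptor interaction analysis with
    empirical-Bayes moderated-t group contrasts. Includes a synthetic cohort
    generator with planted cell types, composition and ligand-receptor
    activity so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    withr
Config/testthat/edition: 3
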