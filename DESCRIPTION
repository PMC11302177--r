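Package: wpcna
Title: Weighted Protein Co-Expression Network Analysis for Multi-Batch TMT
    Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end pipeline for systems-level analysis of isobaric
    (TMT) labelled brain proteomic cohorts. Implements iterative two-factor
    median-polish batch correction against pooled global internal standard
    (GIS) channels, non-parametric bootstrap regression of covariates with a
    protected diagnosis term, robust biweight midcorrelation, signed
    co-expression networks with a mean-denominator topological overlap matrix
    (TOM), hybrid dynamic dendrogram cutting with PAM-style assignment, module
    eigenproteins and kME module membership, iterative module clean-up and
    merging, module-trait correlation and Fisher exact gene-set enrichment,
    permutation Z-summary module preservation and synthetic eigenproteins for
    cross-cohort replication, and TOM-subgraph betweenness-centrality
    bottleneck ranking. A seeded synthetic multi-batch cohort generator with
    planted module structure supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Network, GraphAndNetwork, BatchEffect, Clustering
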