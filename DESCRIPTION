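Package: ccmEC
Type: Package
Title: Cluster Annotation, Expansion Statistics and Spot Classification for Brain Endothelial Single-Cell and Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("CCM", "Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reproducible downstream pipeline for droplet single-cell RNA-seq
    and spot-based spatial transcriptomics of brain endothelial cells in a
    cerebral cavernous malformation (Pdcd10 knockout) mouse model. Provides
    quality control by genotype-wise detected-gene bounds and mitochondrial
    fraction, log-normalization, covariate regression, variable-gene selection,
    graph-based clustering with a clustering-tree stable-region resolution
    heuristic, conserved marker detection with minimum-p combination, rule-based
    cluster annotation from key-gene panels, genotype differential expression
    with uniqueness rules, a confidence-interval cluster-expansion statistic,
    threshold- and quartile-based marker positivity quantification, gene-set
    over-representation with configurable filters, co-expression-rule spot
    classification with Fisher exact comparisons, and a seeded synthetic-data
    generator with ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
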