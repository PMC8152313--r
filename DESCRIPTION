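Package: coexpnet
Title: Gene Co-Expression Network Construction, Module Characterization and
    Differential Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A modular pipeline for weighted gene co-expression network (GCN)
    analysis: optional count and variation filters, correlation networks with
    soft-threshold power selection against scale-free topology, topological
    overlap matrices (TOM), module detection by hierarchical clustering with a
    two-stage dynamic tree cut and eigengene-based module merging, local
    over-representation analysis against GMT gene-set collections, eigengene
    to phenotype association, graph topology tools (hub gene detection by
    connectivity, degree or Kleinberg score; PAM sub-module detection with
    silhouette-based model selection), and two-stage differential
    co-expression between conditions (seven preservation statistics, a
    without-replacement permutation null, and a Z-summary fallback). A
    synthetic-data generator with planted modules and controlled
    cross-condition perturbations makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    igraph,
    jsonlite,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
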