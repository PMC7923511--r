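Package: cytopattern
Title: Pattern Recognition in Binary Cytogenetic Loss-Gain-Fusion Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised pattern recognition for sparse binary matrices of
    cytogenetic Loss/Gain/Fusion (LGF) calls, the band-level encoding of
    patient karyotypes. Provides ten binary distance metrics built on 2x2
    contingency counts, redundant-feature collapsing, Bayesian principal
    component dimension estimation by the Auer-Gervini step function with
    the broken-stick model as a frequentist reference, outlier-feature
    removal by principal component loading lengths, deterministic
    partitioning around medoids, density-dependent down-sampling for graph
    views, thresholded adjacency graphs, classical multidimensional
    scaling, Ward dendrograms with a shared cluster palette, and cluster
    characterization by recurrent cytogenetic event frequencies. A
    synthetic karyotype-cohort generator with full ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
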