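Package: micronet
Title: Co-Occurrence Network Analysis of Vector and Host Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A graph-theoretic framework for disentangling the microbial
    communities carried by an arthropod vector and a vertebrate host across
    habitats. Starting from per-sample genus (or OTU) read-count tables, the
    package applies replicate-consistency merging and read filtering, builds
    weighted genus co-occurrence networks per carrier-by-biotope stratum with
    centrality and modularity community structure, quantifies phylogenetic
    signal (Pagel's lambda) and Faith's phylogenetic diversity on a genus
    tree, scores host specificity from read ratios, and links individual
    carriers by their shared bacterial genera. A synthetic-data generator
    with planted co-occurrence "packets" makes every stage testable without
    external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ape,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    picante,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
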