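Package: scDiversity
Title: Diversity Profiles and Composition Comparison for Single-Cell
    Cluster Occupancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumor (and more generally intra-sample)
    heterogeneity from single-cell RNA-seq cluster assignments using
    Hill-number diversity profiles: the effective number of clusters
    computed across a spectrum of orders q, with richness, exponential
    Shannon, inverse Simpson and Berger-Parker dominance as special
    cases. Companion procedures compare samples or conditions with the
    Kolmogorov-Smirnov distance between discrete cluster occupancy
    distributions, summarize clusters by geometric-mean UMI expression
    and build a Euclidean-distance cluster similarity graph, and assess
    stability of the diversity profile under repeated downsampling of
    cells. Includes readers for 10x-style sparse matrices and
    Loupe-style cluster exports, a negative-binomial synthetic cohort
    generator with known clonal structure, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
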