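Package: chromarch
Title: Comparative Analysis of 3D Chromatin Architecture from Micro-C Contact Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of binned chromosome
    conformation capture (Micro-C/Hi-C) contact matrices: iterative
    correction (ICE) balancing, distance-decay and observed-over-expected
    normalization, stratum-adjusted reproducibility (SCC), A/I/B
    compartment calling from correlation eigenvectors with saddle-plot
    compartmentalization strength and a three-component Gaussian-mixture
    intermediate state, diamond insulation profiles with hierarchical
    boundary classification, focal chromatin-loop calling with aggregate
    peak analysis (APA), promoter/enhancer anchor annotation, promoter-hub
    detection and gene grouping, and orthology-anchored loop-synteny
    conservation tests. Includes a synthetic contact-map generator with
    planted compartments, boundaries, loops, chromatin tracks and paired
    orthologous genomes so that every stage of the pipeline can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
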