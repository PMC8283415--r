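Package: microassembly
Title: Assembly Processes of Abundant and Rare Microbial Subcommunities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infrastructure for dissecting how abundant and rare bacterial
    subcommunities assemble along an environmental stress gradient.
    Partitions OTUs into abundant, moderate and rare classes with fixed
    relative-abundance cutoffs, computes alpha-diversity, Bray-Curtis
    dissimilarity and a Shannon-based resistance index, quantifies Levins'
    niche breadth, fits the Sloan neutral community model with binomial
    confidence bands, classifies pairwise community-assembly processes from
    beta-nearest-taxon-index and Raup-Crick null models, and builds
    Spearman co-occurrence networks with a random-matrix-theory threshold.
    Ships individual-based neutral and dose-response gradient simulators so
    every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    vegan,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Network, Software
RoxygenNote: 7.3.3
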