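Package: noveltynet
Title: Comparing De Novo Amplicon Clustering Approaches for Novel
    Diversity Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to cluster environmental and reference marker-gene
    amplicons (e.g. protist 18S V4) with three de novo approaches --
    greedy centroid clustering at a global identity threshold, sequence
    similarity networks cut into connected components, and iterative
    local-threshold (swarm-style) single linkage with abundance-aware
    chain breaking -- and to audit how each approach delineates novel
    diversity. Exact global pairwise alignment with an all-columns
    identity definition, banded edit distances, multi-source shortest
    paths from environmental to reference amplicons inside OTUs,
    best-hit divergence profiles, three-way overlap of novel amplicon
    sets, and a synthetic community generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    igraph,
    ggplot2,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
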