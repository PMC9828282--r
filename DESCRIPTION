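Package: multipsn
Title: Multiplex Protein-Similarity-Network Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build protein-similarity networks from per-ortholog percent-identity
    matrices, select per-layer identity thresholds at peaks of a network
    dissimilarity profile, assemble the thresholded layers into a multiplex
    network with inter-layer couplings, detect communities by multiplex
    Girvan-Newman edge removal with multilayer modularity tracking, convert the
    removal trace into a dendrogram (Newick export), and quantify community
    support with a binomial resampling bootstrap over identity scores. Includes
    a synthetic planted-block fixture generator for benchmarking and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    ape,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
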