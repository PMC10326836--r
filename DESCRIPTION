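Package: phylosym
Title: Phylogenetic Brownian Models of Microbiota Composition Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a multivariate Brownian motion model of log microbial
    abundances evolving along a host phylogeny to compositional
    (relative-abundance) microbiota tables, treating per-host total
    abundances as latent variables. Jointly estimates phylosymbiosis
    (Pagel's lambda), the ancestral microbiota composition at the root,
    and the evolutionary variance-covariance matrix between microbial
    taxa by Hamiltonian Monte Carlo (No-U-Turn sampler). Includes a
    permutation test for the significance of phylosymbiosis (optionally
    constrained by host traits), generalized least squares ancestral
    reconstruction at internal nodes, centered log-ratio PCA projections
    of ancestral states, covariance-based integration clustering, a
    Mantel-test baseline, posterior-predictive adequacy checks, and a
    forward simulator of microbiota evolution on trees.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    jsonlite,
    phytools,
    Rcpp,
    stats,
    utils,
    vegan
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
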