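Package: ecobnet
Title: Bayesian Network Inference for Zero-Inflated Ecological Abundance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns discrete Bayesian dependency networks from ecological
    abundance tables such as photographic seafloor surveys. Provides
    zero/low/high discretization for zero-inflated counts, rare-taxon and
    chi-squared contingency pre-filtering, BDeu-scored greedy structure
    search with a parent cap, bootstrap consensus networks with
    mixture-model occurrence thresholding and signed influence scores, and
    chain-propagated inference of how forcing one node's state shifts the
    state probabilities of every connected node. Includes a synthetic
    zero-inflated community generator with a known ground-truth network for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    mclust,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
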