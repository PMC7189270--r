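Package: evembed
Title: Event Embedding of Temporal Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Embeds the events of a temporal contact network into a
    low-dimensional vector space. Events become the nodes of a weighted
    directed acyclic event graph whose edges carry a temporal-path weight
    and a co-occurrence weight; per-event contexts are sampled from this
    graph with a tunable mix of the two weights and fed to a Skip-Gram
    model with negative sampling. Includes entropy-based selection of the
    embedding dimension, deterministic SI epidemic simulation seeded at
    every event, regression-based prediction of final epidemic sizes from
    event coordinates, three randomized reference models (snapshot,
    timeline and link shuffling), non-negative CP tensor factorization of
    the contact tensor with core-consistency rank selection, and synthetic
    generators for snapshot-resolved contact sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
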