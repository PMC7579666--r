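Package: cascadyn
Title: Catastrophe Dynamics of Cascading Disasters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models catastrophes as absorbing Markov chains over a generic
    taxonomy of 19 peril classes. Encodes one-to-one trigger probabilities
    between perils in a substochastic adjacency matrix, computes the
    interaction matrix of emergent multi-step cascades via truncated power
    series or the closed-form fundamental matrix, analyses
    topology-dependent cascade expansion and amplification, and provides
    the encoding pipeline for historical catastrophe case lists together
    with directed-graph centrality reports and a Monte Carlo chain
    simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
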