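Package: microkge
Title: Knowledge Graph Embeddings for Microbial Coculture Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents pairwise microbial coculture interactions as a knowledge
    graph whose relations combine an interaction type (positive, negative,
    neutral) with the carbon-source environment in which the interaction was
    measured, and learns low-dimensional embeddings of strains and relations
    with the TransE, DistMult and SimplE scoring models under classical or
    interaction-based negative sampling. The learned embeddings support four
    inference tasks: interaction-type prediction for strain pairs,
    prediction for strains absent from the graph via phylogeny-weighted
    synthetic embeddings, transfer of observed interactions between similar
    environments, and ranking of candidate strains expected to elicit a
    desired interaction with a target strain. A synthetic-data generator with
    controllable class mix, environment redundancy and trait-phylogeny
    correlation makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
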