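Package: semnetrecover
Title: Recovery Simulation for Individual Semantic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A recovery-simulation framework for measuring individual semantic
    networks from behavioral data. Builds a common ground-truth semantic
    network from word-embedding cosine similarities (synthetic embeddings by
    default, external word2vec/fastText vectors optionally), derives a
    population of individualized networks with a triangle-score-guided graph
    perturbation algorithm, simulates free-association and
    relatedness-judgment responses under configurable study designs,
    re-infers networks from the simulated data (PPMI plus cosine for
    associations; rescaled, averaged ratings for judgments), and scores
    recovery as bias (geometric-mean ratio), resolution (Spearman
    correlation), and generalizability, including attenuation-based power
    analysis for downstream group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
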