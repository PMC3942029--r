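Package: mulekit
Title: Discovery and Characterization of Prokaryotic Mutator-Like
    Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for discovering Mutator-like
    (MULE) DDE transposase families in prokaryotes and characterizing the
    transposable elements that encode them. Provides iterative
    profile-based homolog expansion over protein databases, all-against-all
    similarity networks clustered with a Markov Cluster (MCL)
    implementation, transposable-element boundary calling from multi-copy
    genomic evidence with terminal inverted repeat (IR) and target-site
    duplication (DR) validation, insertion-site specificity analysis
    around sigma-A promoters, sliding-window alignment conservation
    profiling with DDE-triad anchoring, and a synthetic-data generator
    that plants elements with known truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
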