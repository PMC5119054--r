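Package: depnet
Title: Syntactic Dependency Networks: Construction, Diagnostics, and Group Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds word-type syntactic dependency networks from dependency
    treebanks (CoNLL-X/CoNLL-U or a tabular dependency-list dialect), computes
    the standard complex-network measure battery (degree, clustering
    coefficient, average path length, betweenness and closeness centrality,
    degree distributions with log-log power-law fits), issues small-world and
    scale-free verdicts against size-matched binomial G(N,M) random-graph
    nulls, and compares two corpora with nonparametric tests on vocabulary
    richness, function-word usage, and per-vertex network measures. Includes a
    Zipf-lexicon synthetic treebank generator so the whole pipeline can be
    exercised without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
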