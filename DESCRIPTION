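Package: spedner
Title: Hybrid Dictionary-Based Biomedical Named-Entity Recognition with
    Shortest Path Edit Distance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Dictionary-based recognition of biomedical entity mentions
    (proteins, genes, diseases, chemicals) in text, robust to the spelling
    variation typical of gene and protein names ("EGR-1", "Egr 1", "egr-1").
    Builds and merges entity dictionaries from multiple tabular sources
    including MeSH-tree-style category tables, generates candidate matches by
    weighted approximate lookup over a trie, ranks candidates with the
    Shortest Path Edit Distance (a piecewise string metric computed as a
    normalized shortest path over an alignment lattice with a common-prefix
    re-scorer), and merges overlapping candidate mentions using part-of-speech
    and stemming cues. Includes a seeded synthetic-corpus generator, strict
    precision/recall/F1 evaluation with IOB2 reading and writing, k-fold
    splitting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
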