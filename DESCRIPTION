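Package: sigpevo
Title: Evolutionary Analysis of Signal Peptide Gain and Loss in Bacterial Ortholog Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how cleavable Sec signal peptides are gained and
    lost across orthologous bacterial protein families. Implements consensus
    secretion-state calling from multiple predictor outputs, Fitch parsimony
    reconstruction of ancestral signal-peptide states on rooted gene trees,
    an annotation-aware gene start correction step between two rounds of
    parsimony, branch-level gain/loss event calling with taxonomic placement,
    classification of event mechanisms (whole-segment indel versus point
    substitution) via N-terminal length ratios, and lifestyle-association
    statistics including a per-cluster discrimination score and enrichment
    tests. A synthetic-data generator produces fully ground-truth-labelled
    ortholog families (species trees, sequences, predictor calls, annotation
    errors) so the entire pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
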