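Package: poised
Title: Signal-Induced Selective mRNA Decay Analysis from Metabolic Labeling and CLIP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for studying signal-induced selective
    mRNA decay at 3'UTR termini. Provides a ground-truthed synthetic-data
    generator (3'UTR sequences with planted poly(A)-signal-anchored AUU
    motifs, condition-dependent protein-RNA cross-link tracks, metabolic
    labeling decay kinetics and expression/differential-expression tables),
    exponential half-life estimation from conversion time courses,
    gradient-boosted classification of stability direction with dual feature
    importances, positional k-mer enrichment at cross-link sites with
    substring-Jaccard/rank UPGMA motif-group clustering, expression-normalized
    cross-link metaprofiling around 3'UTR termini, and a scaled-down
    convolutional-recurrent sequence classifier with gradient-based
    nucleotide attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    xgboost,
    pROC,
    IRanges,
    S4Vectors,
    Biostrings,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
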