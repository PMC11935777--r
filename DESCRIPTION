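Package: ppitriad
Title: Sequence-Based Protein-Protein Interaction Prediction with Spaced
    Triad Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions from amino-acid
    sequence alone. Six feature encoders (conjoint triads, spaced
    conjoint triads, a dataset-level position-specific scoring matrix,
    AAindex physicochemical property means, Kyte-Doolittle/Hopp-Woods
    hydropathy means, and amino-acid pairwise distance) turn each
    protein into a fixed-length numeric vector; pair vectors feed a
    dense neural classifier with batch normalization, LeakyReLU,
    dropout, Adam, early stopping and checkpointing. Includes stratified
    k-fold cross-validation with a full confusion-matrix metric suite,
    a synthetic planted-motif data generator for end-to-end testing,
    readers for FASTA, interaction-pair tables and the AAindex1 flat
    file, and broom-style tidiers plus ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
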