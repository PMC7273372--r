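Package: enzid
Title: Human Enzyme Identification from Protein Sequences with CKSAAP Features and SVM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A sequence-based toolkit for classifying human enzymes versus
    non-enzymes. Implements amino acid composition (AAC) and composition of
    k-spaced amino acid pair (CKSAAP) feature encodings, two-group ANOVA
    F-score feature ranking with incremental forward selection, an RBF-kernel
    support vector machine with log2 grid search and k-fold cross-validation,
    and confusion-matrix/ROC evaluation. Includes a seeded synthetic sequence
    generator with controllable k-spaced pair enrichment so every pipeline
    stage is testable without external data, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
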