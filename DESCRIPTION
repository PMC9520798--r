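Package: phisite
Title: Phosphohistidine Site Prediction from Protein Sequence Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies histidine residues in protein sequences as
    phosphohistidine (pHis) or non-pHis sites. His-centered local sequence
    windows are encoded into thousands of named features drawn from 26
    encoder families (amino acid composition, grouped composition, C/T/D,
    conjoint triads, quasi-sequence-order, pseudo amino acid composition,
    autocorrelation, and positional one-hot/AAindex/BLOSUM62/z-scale
    expansions), the most discriminative features are selected by ANOVA
    F-score, and class-weighted classifiers (weighted RBF-kernel support
    vector machine by default) are trained and evaluated with
    imbalance-aware metrics and leak-free stratified cross-validation.
    Includes positional residue-enrichment analysis, greedy identity-based
    redundancy reduction of sequence windows, and a seeded synthetic-data
    generator with planted positional motifs for end-to-end validation.
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
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
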