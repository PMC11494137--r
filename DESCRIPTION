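Package: idpmoments
Title: Moment-Based Sequence Features and Deep Classifiers for Protein Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies proteins as ordered or intrinsically disordered
    (lipid-binding) from primary sequence alone. Sequences are reduced to a
    fixed 150-value descriptor built from residue frequencies, position
    incidence matrices on the forward and reversed sequence, accumulative
    position vectors, and a square sequence grid, each matrix summarized by
    raw, central, and discrete Hahn moments up to order three. Six trainable
    neural classifier heads (1-D CNN, DNN, MLP, RNN, LSTM, GRU) with a
    built-in backpropagation engine score the descriptors, and an evaluation
    harness provides stratified k-fold cross-validation, independent-test and
    self-consistency protocols, ROC/AUC, confusion-matrix metrics (accuracy,
    sensitivity, specificity, MCC, F1), and decision-boundary maps. A seeded
    Markov-chain sequence generator produces labeled benchmark-shaped
    datasets for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
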