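Package: circsites
Title: Convolutional Classification and Motif Discovery for circRNA
    Protein-Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies RNA-binding-protein binding sites on circular RNA
    sequence fragments with a multi-branch convolutional network trained on
    one-hot encoded 100-nt fragments, and converts the learnt convolution
    kernels into sequence motifs in MEME minimal format. Includes the full
    dataset-construction pipeline (length filtering, peak-centred extension,
    deduplication, dinucleotide-preserving shuffle negatives, pair-coupled
    train/validation/test splits), k-mer baseline classifiers, rank-based
    ROC/AUC evaluation, and a planted-motif synthetic data generator for
    benchmarking the whole pipeline without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    e1071,
    nnet,
    randomForest,
    readr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
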