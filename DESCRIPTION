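Package: dhloop
Title: Deep Hybrid Learning for Chromatin Loop Prediction from DNA Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts chromatin loops (ChIA-PET style anchor-pair
    interactions) from genomic sequence alone. Builds paired 256 bp
    anchor-window datasets from FASTA genomes and BEDPE interaction calls,
    featurises sequence pairs with overlapping k-mer frequency vectors,
    trains support vector machine, random forest and k-nearest-neighbour
    classifiers alongside a pluggable deep sequence-pair classifier, and
    combines their binary decisions with a Boolean majority-vote fusion
    rule (deep hybrid learning). Ships a synthetic motif-planted genome
    simulator so the full pipeline is testable at desk scale, plus the
    six-metric evaluation panel (accuracy, precision, recall, F1, Matthews
    correlation coefficient, ROC AUC) and precision-recall AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
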