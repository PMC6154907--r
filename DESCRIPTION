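Package: viroscu
Title: Virus Detection in Metagenomic Contigs from Relative Synonymous Codon Usage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies assembled metagenomic contigs as viral or non-viral from
    their relative synonymous codon usage (RSCU). Open reading frames are scanned
    on both strands of every contig, per-strand codon counts are converted into a
    59-dimensional RSCU feature vector, and random-forest or feed-forward
    neural-network classifiers estimate the probability that a contig is viral.
    Evaluation uses leave-one-experiment-out cross-validation with micro- and
    macro-averaged ROC curves, per-class precision/recall at a chosen threshold,
    and precision-recall trade-off curves; Gini impurity importance averaged
    across trees ranks the codons driving the classification. A synthetic contig
    generator with planted codon-usage differences, configurable class
    prevalence, per-experiment batch effects and optional indel noise makes the
    whole pipeline testable without external data.
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
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
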