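Package: gapfseq
Title: Palindrome-Enrichment Sequencing Profiles and Tumor DNA Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of sequencing libraries enriched for DNA palindromes
    (fold-back inversions). Counts aligned reads into fixed-width genomic
    bins with mapping-quality filtering, normalizes to per-million coverage,
    curates a blocklist of recurrent artifact bins, ranks high-coverage bins
    (HCBs) and summarizes their chromosomal and cytoband distribution, and
    calls tumor versus normal DNA with a per-chromosome HCB-count threshold
    classifier (ROC, trapezoidal AUC, Youden's J, seeded cross-validation).
    Includes a comparative machine-learning evaluation with permutation
    feature importance, a scanner for same-orientation (FF/RR) read pairs
    at fold-back junctions, an insert-size partitioner, and a synthetic
    cohort simulator that provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    pROC,
    optparse
Config/testthat/edition: 3
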