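Package: hybridbin
Title: Parent-of-Origin Classification of Hybrid RNA-Seq Read Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns paired-end RNA-seq read pairs from an interspecies
    hybrid to their parent of origin. Read pairs aligned separately to the
    two parental references are converted into a 53-feature vector
    summarising alignment scores, edit distances, mismatch and indel
    events (with high-quality variants keyed to base-call quality), and a
    random forest post-processor is trained to choose the better parent.
    Includes the two alignment-only baselines (aligner choice on
    concatenated references, alignment-score comparison with random tie
    breaking), a binary-classification metrics panel (accuracy through
    MCC, AUPRC, AUROC and positive-class preference), and a synthetic
    hybrid simulator that emits diverged parental references,
    error-bearing paired reads and ground-truth SAM with exact AS/NM/MD
    tags, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Rsamtools,
    ranger,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
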