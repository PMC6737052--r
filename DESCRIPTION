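Package: netfactor
Title: Network-Based Identification of Transcription Factor Regulators of
    Expression Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies the most significant, non-redundant set of
    transcription factor (TF) regulators of a multi-gene expression
    biomarker. From a gene expression matrix with case/control labels, a
    candidate TF list and a biomarker gene set, the package infers an
    ARACNE-style context-specific gene regulatory network (mutual
    information, data processing inequality pruning, bootstrap consensus),
    scores each TF's differential activity between classes by regulon
    enrichment of a differential-expression signature against a
    permutation null, tests each regulon for biomarker over-representation
    with Fisher's exact test, and solves an L1-relaxed weighted set-cover
    linear program whose weights rank the TFs. Includes a greedy coverage
    baseline, robustness comparisons between networks, activity scores and
    ranked regulator lists, and a ground-truthed synthetic-data generator
    with planted driver TFs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
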