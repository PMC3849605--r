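Package: CysBond
Title: Context-Based Prediction of Disulfide Bonding States and Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts which cysteine residues of a protein chain form
    disulfide bonds and how they are paired. Knowledge-based mean-force
    potentials are derived from first- and second-order neighbourhood
    statistics around cysteines, weighted by sequence profiles (PSSM
    frequencies). The resulting context scores are combined with profile
    windows in two single-hidden-layer feed-forward neural networks (one
    for the per-cysteine bonding state, one for pairwise connectivity),
    and per-pair probabilities are resolved into a consistent disulfide
    pattern by maximum-weight matching. Includes parsers for FASTA,
    PSI-BLAST ASCII PSSM and tabular bond-list annotations, chain-level
    N-fold cross-validation with the standard evaluation metrics, and a
    synthetic corpus generator with planted neighbourhood effects so the
    full train/predict/evaluate loop runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
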