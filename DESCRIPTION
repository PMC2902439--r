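Package: eigencis
Title: Comparative Eigensystem Analysis of Cis-Regulation in Time-Series
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative singular value decomposition (SVD) of two time-series
    gene-expression systems, identification of conserved eigensystems by
    eigenarray correlation on common genes, exact Bayesian parent-set
    selection over composite cis-regulatory motifs with a
    Bayesian-Dirichlet equivalence (BDe) score, permutation q-values and
    cross-system validation, and grouped weighted least-squares regression
    of eigensystem loadings on motif and conserved-non-coding-sequence
    counts with path analysis.  Includes a synthetic paired-dataset
    generator with planted regulatory effects so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lmtest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
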