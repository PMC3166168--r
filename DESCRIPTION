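Package: fissionet
Title: Social Structure Analysis for Fission-Fusion Animal Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the social structure of fission-fusion
    animal populations from repeated scan samples of group membership.
    Computes dyadic association indices (simple ratio, half weight),
    margin-preserving checkerboard-swap permutation tests for non-random
    association, gregariousness and dyadic preference/avoidance, weighted
    social network measures (strength, eigenvector centrality, reach,
    clustering coefficient, affinity) with bootstrap standard errors,
    and lagged association rates over within-session and across-day time
    scales with jackknife precision, exponential decay model fitting by
    binomial quasi-likelihood, QAIC model selection, and between-class
    parameter comparison with false discovery rate control. Includes
    synthetic-data generators (homogeneous, beta-dyadic, bonded Markov,
    spatial arena) emulating a 12-individual scan-sampling study design
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
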