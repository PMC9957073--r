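Package: karyorate
Title: Tempo and Mode of Chromosome Number Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits continuous-time Markov models of haploid chromosome-number
    evolution -- fusions, fissions and whole-genome duplication -- on
    time-calibrated phylogenies in a Bayesian framework. Provides the
    pruning-algorithm likelihood, slice-sampling MCMC with multi-tree
    posterior pooling, highest-posterior-density summaries and the
    normalized fusion/fission rates ratio, a clade-removal sensitivity
    analysis, a sex-chromosome fusion-signal statistic, and a forward
    (Gillespie) simulator of trees and karyotypes so every stage can be
    exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
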