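Package: dfemap
Title: Selection Inference from Polymorphism and Divergence in Coding
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Joint population-genetics and phylogenetics inference of
    natural selection in protein-coding genes from polymorphism within and
    divergence between species.  Implements a multiallelic codon model with
    mutation, selection and drift; an extended Felsenstein pruning
    algorithm in which tree tips carry population samples rather than
    single sequences; a Bayesian sliding-window (change-point) model for
    intragenic variation in population-scaled selection coefficients; and
    Markov chain Monte Carlo machinery to estimate a discrete,
    non-parametric distribution of fitness effects per lineage.  A forward
    Wright-Fisher codon simulator with explicit ancestral-identity
    tracking is included for validation and for generating test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
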