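Package: tomrep
Title: Computational Phenotyping of Reciprocal Social Adaptation in Repeated Dyadic Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates repeated dyadic hide-and-seek games between learning
    agents of calibrated mentalizing sophistication (recursive k-ToM
    meta-Bayesian learners, influence learning, reinforcement learning,
    win-stay/lose-switch, and biased-Nash policies), fits an eight-model
    behavioural repertoire to trial-by-trial binary choice sequences by
    approximate Bayesian model comparison (MAP plus Laplace evidence), and
    derives two computational phenotypes per participant: repertoire
    flexibility and theory-of-mind sophistication.  Includes a synthetic
    cohort generator with ground-truth strategies and symptom scores,
    leave-one-out logistic classification with permutation-based chance
    testing, and phenotype-to-symptom regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
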