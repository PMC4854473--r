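Package: bayesflex
Title: Bayesian Whole-Genome Regression with Flexible Hyperparameter Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression ("Bayesian alphabet") methods for genomic
    prediction of breeding values, including BayesA, BayesB and BayesCpi with
    fixed hyperparameters and their flexible counterparts (BayesFA, BayesFB,
    BayesFCpi) in which the degrees of freedom and scale of the scaled
    inverse chi-square prior on SNP-effect variances are treated as unknown
    and sampled by an accept-reject scheme inside the Gibbs cycle.  Also
    provides GBLUP with an EM-REML variance-component estimator, a
    forward-in-time population simulator at mutation-drift equilibrium with
    candidate QTL placed between adjacent SNPs, genotype quality control and
    mean imputation, and cross-validation / predictive-accuracy evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
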