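Package: rjcthmm
Title: Bayesian Continuous-Time Hidden Markov Models with an Unknown
    Number of States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully Bayesian inference for continuous-time hidden Markov
    models (CTHMMs) with generalized-linear observation models on
    irregularly timed longitudinal data. The number of hidden states is
    treated as unknown and sampled by reversible-jump Markov chain Monte
    Carlo using centered split/combine moves on the infinitesimal
    generator, the initial distribution and the regression coefficients.
    A model-based clustering extension infers, simultaneously, the number
    of mixture components and each component's state count. Includes
    exact endpoint-conditioned path sampling (rejection sampling with a
    uniformization fallback), forward-filtering backward-sampling latent
    path imputation, conjugate and Metropolis-Hastings fixed-dimension
    updates, and a simulator for benchmark data-generating
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
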