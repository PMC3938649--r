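Package: valba
Title: Discounted Value Accumulation Models of Intertemporal Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models intertemporal choice as discounted value accumulation.
    Provides hyperbolic, exponential and quasi-hyperbolic delay-discounting
    value functions with a softmax choice rule, adaptive staircase
    estimation of discount rates, and construction of offers at target
    choice probabilities; closed-form linear ballistic accumulator (LBA)
    defective densities, trial simulation and likelihoods; hierarchical
    Bayesian estimation combining differential-evolution MCMC at the
    subject level with conjugate Gibbs updates at the group level;
    model comparison across condition-constraint variants by the Bayesian
    predictive information criterion; and linkage analyses relating drift
    rates and non-decision times to subjective value. A synthetic-cohort
    generator emulating the two-session task design makes the full
    pipeline testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    nlme,
    yaml,
    jsonlite,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
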