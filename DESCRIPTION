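Package: nmaplan
Title: Evidence-Informed Clinical Trial Planning with Network Meta-Analysis of Relapse Counts
Version: 0.1.0
Authors@R:
    person("Plan", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for planning the next trial in a clinical development
    programme from the totality of existing evidence. Randomised-trial and
    real-world-evidence relapse-count data are pooled at face value in a
    Bayesian random-effects network meta-analysis with a negative binomial
    arm-level likelihood, fitted by an adaptive Metropolis-within-Gibbs
    sampler. Predictive treatment-effect distributions from the fitted
    network drive simulation of future two-arm trials, negative binomial
    regression analysis of each replicate, power and false-positive-rate
    estimation, and minimum sample-size search. Simulated trials can be
    substituted back into the network to quantify the impact of an
    alternative development strategy on the totality of evidence, and
    recruitment timelines can be projected for the re-sized programme.
    Includes a generator for synthetic evidence networks with known truth
    and a curated real-world-evidence fixture for relapsing-remitting
    multiple sclerosis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
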