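Package: stepwedgesim
Title: Simulation and Analysis of Cross-Sectional Stepped Wedge Trials
    with Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating cross-sectional stepped wedge cluster
    randomised trials with binary outcomes and for comparing the analysis
    methods most often applied to them. Trial data are generated from a
    beta-binomial mechanism in which true cluster proportions are drawn
    from a beta distribution calibrated to a target mean and intra-cluster
    correlation, and cell probabilities follow a logistic model in
    treatment and (linear-in-logit) time. Four estimators of the
    intervention effect are provided behind a common fitting interface: a
    random-intercept logistic mixed model fitted by adaptive Gauss-Hermite
    quadrature with containment degrees of freedom, logistic generalised
    estimating equations with an exchangeable working correlation and
    robust (sandwich) variance, logistic regression with fixed cluster
    effects, and a linear mixed model on cluster-period event proportions.
    A scenario-grid harness runs replicate simulations and summarises per
    cent bias, type I error, power, and convergence failures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    parallel,
    graphics,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
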