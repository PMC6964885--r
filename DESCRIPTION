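Package: dcepref
Title: Discrete-Choice Experiment Analysis with Hierarchical Bayes and
    Preference-Weighted Treatment Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and analysing discrete-choice experiments
    (DCEs) in health preference research. Generates balanced-overlap
    fractional-factorial choice designs with dominated-alternative warm-up
    tasks, simulates respondent populations with known preference structure,
    estimates individual part-worth utilities with a hierarchical Bayesian
    multinomial logit fitted by Metropolis-within-Gibbs with Gelman-Rubin
    convergence diagnostics, summarises posteriors as scaled utilities,
    relative importance and marginal rates of substitution, fits latent-class
    logit mixtures by EM, audits internal validity (dominated-task failures,
    straight-lining, attribute dominance), and fuses part-worth posteriors
    with network-meta-analysis outcome distributions to rank treatments by
    preference-weighted benefit-risk. Ships the attribute schema and
    treatment profiles of a Crohn's disease maintenance-therapy application.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
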