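Package: stdcausal
Title: Regression Standardization for Causal Effect Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates counterfactual outcome probabilities by regression
    standardization (the parametric g-formula): conditional predictions from a
    fitted logistic or Cox proportional-hazards model are averaged over the
    empirical confounder distribution at fixed exposure levels, with joint
    cluster-robust (sandwich) variances from stacked estimating equations.
    Standardized probabilities are contrasted into causal effect measures --
    attributable fraction, number needed to treat, relative excess risk due to
    interaction, risk differences and ratios -- with delta-method standard
    errors and Wald confidence intervals on the identity or log scale,
    including time-indexed curves for survival outcomes. Includes seeded
    generators for clustered binary-outcome and right-censored survival data
    with known generative truth, for validation by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    survival,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
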