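Package: ceatree
Title: Decision-Tree Cost-Effectiveness Analysis with Probabilistic
    Sensitivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A config-driven engine for two-strategy decision-analytic
    cost-effectiveness analysis. Builds decision trees from a declarative
    YAML model file, computes expected cost and quality-adjusted life years
    (QALYs) by probability-weighted rollback, performs incremental
    cost-effectiveness analysis (ICER, dominance classification, net
    monetary benefit over willingness-to-pay grids), and quantifies
    parameter uncertainty by Monte Carlo probabilistic sensitivity
    analysis (cost-effectiveness plane, acceptability curves, strategy
    selection frequencies). Parameter uncertainty is specified as mean
    and standard deviation with a named family (Beta or Gamma) and fitted
    by method of moments. A microsimulation module generates synthetic
    individual-level cohorts whose Bernoulli outcomes follow the tree's
    branch probabilities, serving as an independent check on the rollback.
    Ships a worked school-based vitamin D supplementation model for
    adolescent depression prevention.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
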