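Package: episcreen
Title: Entropy-Based Screening of Epistatic Interactions in Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection and characterization of synergistic (epistatic)
    interactions between binary clinical, environmental and psychosocial
    predictors of a binary outcome, built around bronchodilator drug
    response in pediatric asthma. Implements mutual-information main
    effects, pairwise and three-variable information gain with a
    synergy-only subtraction rule, permutation inference with Bonferroni
    familywise control, local case-control subsampling for confounder
    adjustment, a logistic / Firth-penalized regression comparison arm
    with separation and multicollinearity screening, post-hoc
    interaction-group tests, an epistasis network export, and a
    synthetic-cohort generator with penetrance-table interactions of
    configurable (including zero) marginal effect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    boot,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
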