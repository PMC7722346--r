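Package: ltmet
Title: Line x Tester Analysis of Multi-Environment Maize Trials
Version: 0.1.0
Authors@R:
    person("MET", "Tools", email = "met-tools@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for balanced line x tester testcross trials
    evaluated across managed-drought and rain-fed environments. Provides
    plot-level trial ingestion and validation, a synthetic trial generator
    with known ground truth, least-squares genotype means, randomized
    incomplete block ANOVA with variance components and hybrid-mean
    repeatability, general and specific combining ability effects with
    standard errors and Baker's proportion, a standardized multi-trait base
    index for drought tolerance, a rule-based heterotic group classifier
    driven by SCA effects and testcross means, and GGE biplot computations
    (environment-centred SVD, which-won-where sectors, average-environment
    axis stability and ideal-genotype ranking).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
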