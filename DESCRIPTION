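Package: breathcea
Title: Preference Elicitation and Cost-Effectiveness Modelling for
    Breathlessness Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for an economic evaluation of breathlessness-triggered
    support services for older people with advanced disease. Estimates
    patient and carer preference weights for service attributes from
    discrete-choice-experiment data with a conditional logit model
    (cluster-robust standard errors, likelihood-ratio subgroup tests,
    cluster bootstrap), converts fitted utilities into service-uptake
    probabilities, and feeds those into a five-state Markov cohort model
    producing discounted costs, quality-adjusted life years, incremental
    cost-effectiveness ratios, probabilistic sensitivity analysis and
    cost-effectiveness acceptability curves. Includes seedable generators
    for choice data, trial-like cost and utility payoffs and life tables
    so the whole pipeline can be exercised without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
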