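Package: riskwarn
Title: Probabilistic Early Warning of Food Quality and Safety Risk
Version: 0.1.0
Authors@R:
    person("riskwarn", "developers", email = "riskwarn@example.org", role = c("aut", "cre"))
Description: An open, scriptable engine for enterprise food-quality-safety risk
    early warning. Builds expert-weighted risk hierarchies with the analytic
    hierarchy process (principal-eigenvector weights, consistency-ratio
    filtering, weighted geometric aggregation across experts), converts hazard
    detection records to dimensionless risk scores by five-level fuzzy
    membership, elicits risk values from probability-impact questionnaires with
    Cronbach alpha reliability checks, fits candidate probability distributions
    (including the four-parameter BetaGeneral) by maximum likelihood with
    chi-square goodness-of-fit tests and P-P/Q-Q diagnostics, aggregates an
    overall risk value by Latin hypercube Monte Carlo simulation, and ranks risk
    drivers by rank-correlation sensitivity and exceedance scenario analysis
    against warning thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
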