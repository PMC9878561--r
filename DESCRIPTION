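Package: viptask
Title: Simulation and Analysis of the Variable Investment Poker Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying escalation of commitment and premature
    opt-out in incentivized sequential investment decisions with a
    poker-based task. Provides exact (enumerative) and Monte Carlo
    win/tie/loss probabilities for partially revealed Texas hold'em style
    trials, a stagewise invest/opt-out task engine with personal
    responsibility, preference, and gain/loss framing manipulations,
    parametric synthetic participants whose choices follow a logistic
    policy with participant random intercepts, random-intercept logistic
    and linear mixed model fitting with Wald inference and
    simulation-based power analysis, and expected-value scoring of
    decisions against the optimal policy.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
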