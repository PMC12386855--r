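Package: sitdemog
Title: Demographic Efficacy Analysis of Sterile Insect Technique Cage Trials
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing semi-field cage trials of the sterile insect
    technique (SIT) and pyriproxyfen-boosted SIT against Aedes mosquitoes:
    interval-censored stage-transition aggregation with a competing-risks
    correction of the emergence denominator, Bayesian mixed-effect binomial
    logistic regression with an observation-level random effect producing
    posterior draw matrices, Fried competitiveness indices, relative risks of
    adult emergence with credible intervals, a posterior simulation test of
    efficacy loss, a zero-augmented gamma model for ovitrap water
    concentrations of pyriproxyfen, rearing quality indicators, and a
    synthetic-trial generator so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    optparse,
    yaml
Config/testthat/edition: 3
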