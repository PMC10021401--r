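Package: u5mproj
Title: Scenario-Based Subnational Projection of Under-Five Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for projecting county-level under-five mortality (U5M)
    under intervention scale-up scenarios. Provides annual-rate-of-change
    (ARC) arithmetic and exponential projection, multi-stage selection of
    intervention coverage factors (bivariate log-linear screening,
    redundancy exclusion, a principal-component antenatal-care index, and
    elastic-net regression), a Bayesian log-linear spatio-temporal
    mixed-effects ecological model fitted by Markov chain Monte Carlo with
    BYM-type spatial random effects, a scenario engine constructing
    business-as-usual and four coverage scale-up trajectories, and
    counterfactual U5M prediction with SDG 3.2 attainment reporting. A
    synthetic-data generator produces county-year panels with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    coda,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
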