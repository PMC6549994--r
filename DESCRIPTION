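Package: landmarkov
Title: Scenario-Led Land-Use/Land-Cover Change Projection with MLP-Markov Ensembles
Version: 0.1.0
Authors@R:
    person("landmarkov", "developers", email = "landmarkov@example.org",
           role = c("aut", "cre"))
Description: Tools for scenario-led projection of categorical land-use/land-cover
    (LULC) maps: cross-tabulation change analysis between two dates, driver
    variable construction (exact Euclidean distance transforms, evidence
    likelihood of change) and screening by Cramer's V, per-origin-class
    multi-layer-perceptron transition-potential models, Markov-chain change
    demand with declarative scenario editing of the transition probability
    matrix, and greedy ranked spatial allocation of projected change. Includes
    a synthetic-landscape generator with known transition dynamics so the whole
    pipeline is testable without external data, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
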