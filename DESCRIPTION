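Package: edmpc
Title: Empirical Dynamic Modeling Predictive Control of Agent-Based Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven model predictive control from generalized state-space
    embedding. Provides an empirical dynamic modeling (EDM) forecasting core
    (simplex projection and the s-map locally weighted global linear map), an
    agent-based simulator of civil-disobedience dynamics on a toroidal lattice
    (an Epstein rebellion variant with time-varying government legitimacy and a
    controllable propaganda threshold), a logistic feedback controller that
    steers the agent system away from trapped states of sustained rebellion,
    and interaction-strength analyses based on time-varying s-map coefficients
    (Jacobians). Includes deterministic fixture generators, hyperparameter
    scans for embedding dimension and forecast horizon, episode and
    trapped-state detectors, and a train/test forecast-skill protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
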