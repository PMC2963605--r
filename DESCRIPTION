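Package: grnpipe
Title: Gene Regulatory Network Inference from Knock-Out and Time-Series
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Four pipelines for inferring directed gene regulatory networks
    from DREAM4-style expression compendia: median-corrected z-scores on
    steady-state knock-out data (MCZ), time-lagged context likelihood of
    relatedness (tlCLR) combined with L1-constrained ODE regression
    (Inferelator-style), their rank-based combination, and a column-bootstrap
    resampling ensemble aggregated by median rank.  Includes an in-silico
    benchmark generator (sparse signed topologies, ODE dynamics, wild-type /
    knock-out / knock-down steady states, perturbation-relaxation time
    series, double knock-out truth), double knock-out steady-state
    prediction, and evaluation by area under the precision-recall curve and
    relative rank.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
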