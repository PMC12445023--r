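Package: twinscreen
Title: Digital-Twin Signaling Models and In Silico Drug-Response Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds reduced mechanistic ODE models of the Wnt, RAS/MAPK,
    PI3K/AKT/MTOR, Hedgehog and apoptosis signaling axes, individualizes them
    per patient from expression profiles ("digital twins"), simulates
    molecularly targeted drugs to steady state under Monte Carlo parameter
    uncertainty through a kD occupancy law, and summarizes responses with
    Emax, EC50 and growth-rate-inhibition (GR50/GRmax) metrics for
    tumor-versus-normal drug ranking. Also provides the companion in vitro
    analytics: dilution ladders, four-parameter logistic IC50/AUC fits,
    AUC z-scores, therapeutic window scores, Bliss synergy, and morphometric
    growth formulas, together with a synthetic cohort generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
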