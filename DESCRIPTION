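Package: fraclv
Title: Time-Fractional Lotka-Volterra Models with Harvesting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and linear stability analysis of Caputo
    time-fractional predator-prey systems under constant-effort
    harvesting: a two-species model with a Holling type II functional
    response and a three-species extension in which two predator
    species engage in mutualistic predation.  Provides the
    Adams-Bashforth-Moulton predictor-corrector solver for Caputo
    fractional initial-value problems, the Mittag-Leffler function,
    dimensional to dimensionless parameter transforms, closed-form
    equilibria with feasibility reporting, analytic Jacobians, the
    Matignon fractional stability condition with critical-order
    computation, cubic-discriminant root classification, and scenario
    runners that quantify how memory (fractional order below one) and
    harvesting damp population oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
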