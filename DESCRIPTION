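Package: oncoscale
Title: Multistage Carcinogenesis Risk Scaling Across Body Size and Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and approximate multistage (Armitage-Doll-type) models of
    lifetime cancer risk, with extensions for immune policing of cancer cells
    and of driver-mutation-bearing cells. Provides allometric scaling of
    stem-cell compartments and division rates across body sizes, calibration
    of hypothetical small-bodied baselines to a target lifetime risk, inverse
    solvers for the parameter changes (mutation-rate reduction, added driver
    mutations, immune-policing efficiencies) required to stabilize cancer risk
    in large, long-lived species (Peto's paradox), a stochastic lineage
    simulator that serves as a brute-force check on the analytic risk
    formulas, and a report pipeline that tabulates the mouse-to-human and
    mouse-to-blue-whale comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
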