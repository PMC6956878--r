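Package: gocalib
Title: Globally Optimal Range-Restricted Survey Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survey calibration weighting with guaranteed convergence under
    range restrictions. Certifies feasibility of benchmark constraints (BC)
    combined with per-unit weight bounds (RR) by linear programming, computes
    the minimal total absolute error in benchmark totals (TAE*) or the minimal
    total absolute change in bounds (TAC*) needed to restore feasibility, and
    then solves the modified chi-square (GREG) distance calibration problem to
    global optimality. Includes calibration estimation of population totals,
    delete-a-group jackknife standard errors over primary sampling units,
    standard fitting-error metrics, weight diagnostics, a deterministic
    generator of census-versus-survey synthetic scenarios with small and empty
    benchmark cells and inconsistent totals, delimited-text input/output, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    optparse,
    withr
Config/testthat/edition: 3
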