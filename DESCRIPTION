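Package: emobook
Title: Agent-Based Simulation of Emotional Bookkeeping in Primate Groups
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An event-driven agent-based simulator of primate-like individuals
    whose partner-specific affiliative valuations ("LIKE" attitudes) are built
    up by received grooming and eroded during periods without it. Four
    bookkeeping dynamics are supported (linear or logistic increase crossed
    with exponential or logistic decrease), calibrated so that the speed
    parameters LINC (increase) and LHW (decrease half-way time) have exact
    timing semantics. The package provides the closed-form attitude update
    rules, a continuous toroidal world with perception, behaviour selection
    under LIKE-partner selectivity, a fast compiled event loop with lazy
    attitude decay, a relationship-quality analysis suite (category counts,
    second-year averaging, transition R-squared stability scores), a factorial
    parameter-sweep driver, and a synthetic dyadic snapshot generator for
    testing the analysis stage without simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
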