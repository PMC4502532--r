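Package: pggscore
Title: Reputation Scoring and the Evolution of Cooperation in Group Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Agent-based Monte Carlo simulation and mean-field replicator
    analysis of a public goods game in which players carry a binary reputation
    score and are matched into groups by score ranking. Implements three
    scoring rules -- image scoring (reputation from one's own last
    contribution), group scoring (reputation from one's group's last
    performance), and a per-player probabilistic hybrid of the two -- together
    with Fermi-rule imitation dynamics, ensemble experiments and parameter
    sweeps over population size, rate of return and information quality, and a
    four-class (action x score) replicator stability analysis with interior
    fixed points and perturbation probes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
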