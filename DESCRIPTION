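Package: anttrail
Title: Agent-Based Simulation of Pheromone-Mediated Ant-Trail Traffic
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic agent-based simulator of ant traffic on a periodic
    one-dimensional trail, where each ant's velocity is set by the pheromone
    concentration in the cell ahead (chemotaxis) under hard-core exclusion.
    Includes fundamental-diagram (flow-density) measurement with
    critical-density estimation, platoon detection, evaporation- and
    emission-rate sweeps, and the closed-form pheromone aggregation and
    depletion calculus that yields the three stigmergic communication states
    (minimal, active, inactive) and their analytic boundaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
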