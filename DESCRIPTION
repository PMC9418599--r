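Package: tapjid
Title: Joint-Interval Distributions and Cluster-Corrected Regression for
    Smartphone Touchscreen Dynamics
Version: 0.1.0
Authors@R:
    person("Tapjid", "Maintainers", email = "maintainers@tapjid.org",
           role = c("aut", "cre"))
Description: Tools for digital phenotyping from smartphone touchscreen
    event streams. Segments raw touch logs into usage sessions, builds
    joint-interval distributions (JIDs) of consecutive inter-touch
    intervals via two-dimensional Gaussian kernel density estimation on a
    fixed log10 grid, scores standard online cognitive tests (reaction
    times, task switching, Corsi block span, 2-back d-prime), and links
    each JID bin to age or cognition with mass univariate robust
    regression corrected by two-dimensional cluster-based bootstrap
    statistics. Includes residual-based pace-of-aging pair analysis and a
    fully synthetic cohort generator so the whole pipeline is testable
    without any participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
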