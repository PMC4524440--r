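Package: oncoprev
Title: Branching-Process Simulation of Preventive and Post-Diagnostic
    Cancer Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time multitype branching-process simulator of tumour
    growth under constant low-impact treatment. Cells are classified by the
    number of accumulated driver mutations and by resistance status; each
    4-day cell cycle every cell divides or dies, with division optionally
    passing a driver or resistance mutation to one daughter. The package
    implements preventive, post-diagnostic (resection plus therapy) and
    second-chance intervention protocols, parameter sweeps, an exact
    expectation (mean-field) recursion used as an analytic oracle, and
    distributional summaries of detection and relapse times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
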