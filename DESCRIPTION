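Package: stillreg
Title: Population-Based Pregnancy Registry Stillbirth Analysis
Version: 0.1.0
Authors@R:
    person("Registry", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing stillbirth outcomes in prospective,
    population-based pregnancy registries run over geographic clusters in
    low-resource settings. Implements delivery-outcome classification
    (fetal death at >= 20 weeks gestation, or >= 500 g when gestational age
    is unavailable), enrollment accounting, a six-level hierarchical
    cause-of-stillbirth classifier (trauma, congenital anomaly, infection,
    asphyxia, prematurity below 32 weeks, unknown), stillbirth rates per
    1000 births with Wilson or cluster-robust confidence intervals, a
    continuing-cluster restriction for yearly trends, and log-link binomial
    relative-risk models with cluster-robust (generalized estimating
    equation) variance. A seeded synthetic registry generator with a known
    truth ledger makes the whole pipeline testable without access to study
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
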