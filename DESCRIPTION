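Package: evosoc
Title: Evolving-Network Simulator of Societal Standstill, Collapse and Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a model society of occupations coupled through a binary
    directed support matrix and restricted by a shared environment. Equilibria
    of the productivity dynamics are Perron-Frobenius eigenvectors of the
    support matrix; a stochastic mutation phase transfers productivity quanta
    between occupations, creating and regenerating occupations over time.
    Scenario engines for parasitic support, pulse environmental disturbance,
    peaceful invasion and mutual support reproduce the standstill, collapse and
    growth transition patterns, with a Monte-Carlo replication harness,
    extinction statistics and Shapiro-Wilk normality summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
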