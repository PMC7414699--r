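Package: psepath
Title: Path-Specific Effect Statistics for Differential Pathway Analysis
    in Causal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and testing of path-specific causal effects in
    directed acyclic graphs for two-group (case versus control, exposure
    versus non-exposure) comparisons in systems epidemiology.  The effect
    transmitted along one chosen directed path is estimated as the product
    of per-edge back-door-adjusted average causal effects, standardized by
    a bootstrap standard error within each group, and the two standardized
    effects are compared with permutation and bootstrap confidence-interval
    tests.  Includes directed-path enumeration with automatic per-edge
    adjustment sets, network simplification, estimators for continuous,
    binary and ordered discrete variables, and a Monte-Carlo harness for
    type-I-error and power studies on synthetic logistic and linear-Gaussian
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
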