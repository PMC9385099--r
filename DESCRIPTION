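Package: pathsem
Title: Topology-Based Pathway Enrichment with Structural Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene set analysis for signed, directed pathway graphs. Each
    pathway is modelled as a linear structural equation model augmented
    with an exogenous binary group node, giving marginal group-effect
    tests for source and singleton genes and conditional tests (given
    graph parents) for connectors and sinks. Node-level two-sided
    p-values are obtained from a permutation null summarised by its
    first two moments, then combined across the pathway with Brown's
    method for dependent one-sided tests into activation and inhibition
    scores, a Bonferroni pathway p-value, and an up/down perturbation
    call. Includes a decorrelated mean-difference multivariate
    comparator, a synthetic pathway and expression data generator, and
    a simulation harness estimating type I error and power under
    topology-driven gene dysregulation designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
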