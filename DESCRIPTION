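Package: connstab
Title: Numerical Stability of Connectome Pipelines via Monte Carlo Arithmetic
Version: 0.1.0
Authors@R:
    person("Alex", "Moreau", email = "alex.moreau@example.org",
           role = c("aut", "cre"))
Description: Simulates Monte Carlo Arithmetic (MCA) perturbations -- random
    rounding at a configurable virtual precision -- through a synthetic
    structural-connectome reconstruction pipeline, and quantifies the numerical
    stability of the resulting brain networks. Provides normalized percent
    deviation, significant-digit estimation, the discriminability statistic
    with block permutation testing, graph-theoretic feature stability (moments
    and cumulative distributions), and the variability of a downstream
    PCA + logistic-regression phenotype classification under perturbation
    resampling. Includes a hierarchical synthetic-cohort generator
    (subject / session / subsample / phenotype) emulating a repeated-measures
    test-retest design, an experiment orchestrator with YAML configuration,
    and readers/writers for dense adjacency matrices and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
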