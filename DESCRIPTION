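Package: affinitree
Title: Asymmetric Cluster Affinity and Cluster Support Costs for Rooted Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing rooted binary phylogenetic trees with the
    asymmetric Cluster Affinity (CA) cost, the cluster-size-normalized Cluster
    Support (CS) cost, the one-sided Robinson-Foulds distance, and the
    separation cost that quantifies the asymmetry of CA.  Provides exact
    diameters for normalization, extremal tree constructions (caterpillars,
    reversed caterpillars, perfectly balanced and 2-caterpillar trees),
    NNI and SPR edit operations, an incremental data structure that maintains
    CA costs along NNI walks in logarithmic time per step, a birth-death
    topology simulator, and tidy study pipelines reproducing cost
    distribution and robustness experiments on simulated trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
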