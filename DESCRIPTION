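Package: firestem
Title: Spatial Dynamics of Fire-Caused Tree Mortality in Stem-Mapped Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how fire reshapes tree spatial patterns in
    stem-mapped forest plots. Provides a marked-point-pattern data model for
    tree censuses, generators for synthetic stands (clustered, size-segregated
    historical stands versus dense, intermixed contemporary stands), a
    density-dependent crown-consumption surrogate and logistic mortality
    classification, estimators for pair correlation functions, mark
    variograms and r-mark correlation functions with translation edge
    correction, Monte Carlo null models (inhomogeneous Poisson, random
    labeling, random marking) with studentized global envelope tests and
    r-averaged z summaries, tree-group identification by limiting-distance
    chaining with pre/post-fire group flow matrices, and rank-sum plus
    signed-likelihood-ratio comparisons of group-size distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
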