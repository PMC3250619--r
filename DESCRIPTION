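Package: genecut
Title: Estimating the Number of Clusters in Replicated Gene-Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grouping genes according to their expression profiles
    across replicated treatment conditions. Implements six classical estimators
    of the number of clusters (Calinski-Harabasz, Hartigan, cubic clustering
    criterion and a principal-component-box variant, average silhouette, and
    the gap statistic), all evaluated along hierarchical dendrogram cuts in a
    Mahalanobis geometry driven by the pooled within-gene covariance, together
    with the gDGC procedure: a Monte-Carlo test on the dendrogram root-node
    distance that yields a significance-calibrated cut height and groups of
    genes sharing a common expression profile. Includes a synthetic-data engine
    that emulates residual matrices from self-self microarray experiments and
    generates candidate-gene expression matrices with known cluster structure,
    plus a benchmark harness summarising estimator bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
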