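Package: coexpnet
Title: Guilt-by-Association Gene Prioritization from Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by their co-expression
    connectivity to a reference set of known disease genes. Builds pairwise
    Pearson or Spearman correlation networks per individual, combines them
    with inverse-variance weights, declares significant edges at a
    genome-wide top-quantile |r| cutoff, scores candidates with discrete
    (K*) and continuous (K) connectivity, and selects prioritized genes via
    a resampling-based empirical false discovery rate. Includes principal
    component angular ordering of correlation matrices, thresholded network
    export, group comparisons against external annotations, and a latent
    factor synthetic-data generator for end-to-end benchmarking.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
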