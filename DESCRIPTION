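Package: scpilot
Title: Synthetic Single-Cell RNA-Seq Data from Small Pilot Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deep generative modelling of single-cell RNA-seq count data for
    experimental design from small pilot studies. Implements a deep Boltzmann
    machine with negative-binomial visible units (an exponential-family
    harmonium), trained by persistent contrastive divergence with a mean-field
    positive phase and interleaved regularized Fisher-scoring refreshes of the
    per-gene inverse dispersion, and a minimal negative-binomial variational
    autoencoder with both posterior and prior sampling. Synthetic datasets
    generated from pilot subsamples are scored against a reference clustering
    of the original data with the Davies-Bouldin index, the adjusted Rand
    index, cluster-proportion deviations and per-gene summary-statistic
    deviations, supporting sample-size planning for single-cell experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    uwot
Config/testthat/edition: 3
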