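Package: adexpr
Title: Relative Fit and Absolute Adequacy of Phylogenetic Models for Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Brownian-motion, Ornstein-Uhlenbeck and early-burst models of
    continuous trait evolution to per-gene expression levels measured across
    species, with per-species measurement error entering as a fixed additive
    variance. Models are compared by AIC and Akaike weights, and the best model
    is then tested for absolute adequacy: its parameter estimates rescale the
    phylogeny to a unit tree on which, if the model were true, phylogenetic
    independent contrasts are i.i.d. standard normal; five summary statistics of
    the contrasts are compared against a parametric-bootstrap null to yield
    two-tailed p-values per gene. Includes count normalization (CPM, RPKM, TPM),
    replicate summarisation, Blomberg's K, a synthetic-data generator for trees
    and expression matrices, and a study-level pipeline emitting tidy per-gene
    and summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
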