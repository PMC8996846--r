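Package: rngxe
Title: Reaction-Norm Analysis of Genotype-by-Environment Interaction in
    Livestock Herd-Books
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step reaction-norm pipeline for quantifying
    genotype-by-environment interaction (GxE) in livestock phenotypes.
    Step one estimates a continuous herd-environment gradient from the
    fixed herd-environmental-group solutions of a repeatability animal
    model; step two fits a random-regression sire model on that gradient
    (Legendre intercept and slope per sire) with heterogeneous residual
    variance classes, by Gibbs sampling.  Downstream tools compute
    variance and heritability gradients along the reaction norm (ZGZ'),
    estimated-breeding-value re-ranking diagnostics, least-square-means
    contrasts of genetic variance across environmental categories, and
    multivariate breeder's-equation selection responses per environment.
    Includes a synthetic herd-book generator with known reaction-norm
    architecture, pedigree completeness metrics and Henderson's
    relationship-matrix inverse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
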