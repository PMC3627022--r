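Package: densdep
Title: Density Dependence Across Tree Life Stages in Mapped Forest Plots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of conspecific density dependence in fully
    stem-mapped forest dynamics plots. Later life stages are analysed with
    grid-based spatial point-pattern statistics (pair correlation function,
    Ripley's K and L) under case-control random-labeling null models that
    factor out habitat heterogeneity, with Monte Carlo simulation envelopes
    and a Loosmore-Ford goodness-of-fit test; density-dependent thinning
    between sapling and juvenile stages is quantified by the change in
    additional aggregation d(r) and its maximum d_max. Early stages are
    analysed with binomial mixed-effects models of seedling survival driven
    by conspecific and heterospecific neighbourhood densities, compared
    across a nine-model set by AIC. A synthetic-forest generator with
    recorded ground truth makes every stage of the pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
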