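Package: pfnorm
Title: Normalization Methods for Multivariate Platelet Function Time Series
Version: 0.1.0
Authors@R: person("pfnorm", "developers", role = c("aut", "cre"),
    email = "pfnorm@example.org")
Description: Tools for normalizing multivariate perioperative platelet
    function time series (ROTEM, light transmission aggregometry, multiple
    electrode aggregometry, blood counts). Implements four normalization
    transforms (z-score, range, proportion, interquartile-range robust
    scaling) under three grouping scopes (whole dataset, per attribute, per
    time point), the derived ROTEM parameter PLTEM (EXTEM minus FIBTEM),
    Spearman rank correlation with clinical strength classification, pooled
    polynomial trend fitting over ordered time points, and a Gaussian-copula
    synthetic study generator emulating a 20-patient, 3-timepoint
    cardiopulmonary-bypass cohort with controlled marginal ranges and target
    rank correlations. A pipeline runner produces the full method-by-scope
    grid of normalized tables, correlation and trend summaries, and faceted
    comparison figures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
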