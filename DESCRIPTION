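Package: betanet
Title: Beta-Series Functional Connectivity and Graph-Theoretic Network
    Characterization for Event-Related fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for task-state functional connectivity from event-related
    fMRI designs using the beta-series correlation method: single-trial
    general linear model estimation with the canonical double-gamma
    hemodynamic response function, condition-wise region-by-region Pearson
    correlation matrices with Fisher z transformation and group averaging,
    dense threshold-sweep binarization with average-degree and
    clustering-coefficient curves, and Monte-Carlo comparison against
    Erdos-Renyi random-graph nulls.  Includes a synthetic-data generator
    that plants condition-dependent trial-amplitude covariance in
    region-level BOLD signals, behavioral retention scoring, and the
    accompanying repeated-measures ANOVA battery with Greenhouse-Geisser
    correction and Bonferroni post-hoc comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    MASS,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
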