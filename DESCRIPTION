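Package: gridtrend
Title: Grid-Standardized Hierarchical Trend Estimation for Count Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population trends from unbalanced, spatially biased
    count-survey data such as the International Waterbird Census. Sampling
    units are standardized on a square metric grid, and trends are modelled
    with a three-level hierarchical Poisson model: site intercepts, nested
    random year slopes at the grid-cell and site levels with a latitude
    effect on cell mean slopes, and observation-level lognormal
    overdispersion. The marginal likelihood is maximized with a Laplace
    approximation. Includes Moran's I tests on relative neighborhood graphs
    for spatial-autocorrelation diagnosis, delta-method percentage-decline
    summaries, trajectory interval bands, and a synthetic-data generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    geosphere,
    ape,
    igraph
Config/testthat/edition: 3
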