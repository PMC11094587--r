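Package: edmforecast
Title: Simplex Projection and S-Map Forecasting with Explicit Library Bookkeeping
Version: 0.1.0
Authors@R: person("PBS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Empirical dynamic modelling (EDM) for univariate and multivariate
    time series: first-differencing, delay embedding into a lagged state
    space, construction of the library of candidate nearest neighbours with
    explicit focal-point validity and exclusion rules, a closed-form library
    size, simplex projection and S-map forecasting, leave-one-out evaluation
    of forecast skill by Pearson correlation, and embedding-dimension
    selection. All intermediate quantities (neighbour times, distances,
    weights, local coefficients) are returned for inspection and
    cross-implementation comparison. Includes seed-deterministic synthetic
    data generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
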