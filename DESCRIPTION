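Package: fracstab
Title: Stability Machinery for Fractional-Order Delayed Logistic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stability analysis for fractional-order logistic population models
    with discrete and distributed delay. Provides critical-curve boundaries for
    the Caputo logistic equation with a discrete delay, linear-chain-trick
    reductions of two exponentially distributed delay models to incommensurate
    fractional-order systems, the minimum-argument root test with its
    instability measure (IMFOS), parameter-plane stability maps, and an
    Adams-Bashforth-Moulton predictor-corrector integrator that exhibits the
    predicted convergent and periodic regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
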