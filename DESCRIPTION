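Package: rexmeta
Title: Exact Random-Effects Meta-Analysis for Rare Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact inference for random-effects meta-analysis of a two-arm
    treatment contrast when events are rare and the number of studies is
    small. Study-specific event counts are modelled as Poisson with a
    Beta-distributed treatment contrast; conditioning each study on its
    total event count removes the baseline-rate nuisance parameter and
    justifies dropping double-zero studies. Confidence intervals for the
    mean contrast are obtained by inverting Monte-Carlo tests along the
    boundary of the constrained (mean, variance) parameter space, with
    method-of-moments estimators extended to unbalanced designs through
    hypergeometric resampling weights. Includes a simulation harness for
    operating characteristics under a Poisson-Gamma generating mechanism
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
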