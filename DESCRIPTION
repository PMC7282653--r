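Package: fracret
Title: Fraction-Retention Non-Inferiority Tests via Generalized p-Values
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tests of the fraction-retention non-inferiority hypothesis
    that a new treatment retains at least a fraction delta0 of an active
    control's effect over placebo, on the ratio of mean differences.
    Implements the generalized p-value (GPV) test built from generalized
    pivotal quantities for the ratio of two heteroscedastic normal means,
    together with the three summary-statistics competitors (Rothmann's
    test, Wang's test, and the ratio test whose null law is the
    Cauchy-like distribution of a ratio of normals), numerically exact
    distribution functions for that Cauchy-like law, and seeded Monte
    Carlo machinery for type-I-error and power studies. Includes the
    Xeloda colorectal-cancer trial summary data as a worked example and a
    command-line interface.
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
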