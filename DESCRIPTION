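Package: physmig
Title: Residual-Method Estimation of Inter-Prefectural Physician Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based estimation of net physician migration between
    prefectures from biennial workforce stocks and annual licensing counts.
    National attrition (deaths and retirements) is estimated as the residual
    between licensing and stock growth, allocated to prefectures in proportion
    to their mean physician stock, and combined with observed stock changes to
    yield per-prefecture net migrant counts and migration ratios. Includes a
    four-group classification of prefectures by migration ratio, simple and
    multiple linear regression of migration ratios on socio-demographic
    covariates, a synthetic panel generator with known migration ground truth
    for validation, and an end-to-end reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
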