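Package: lurok
Title: Land-Use Regression and Ordinary-Kriging Hybrid Exposure Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds hybrid air-pollution exposure models that combine
    land-use regression (partial least squares, random forest, or
    supervised stepwise linear regression with sign-plausibility and
    variance-inflation screening) with ordinary kriging of the regression
    residuals.  Includes hierarchical temporal averaging of hourly
    monitor data under completeness criteria, leave-one-site-out
    cross-validation with mean-squared-error-based R-squared metrics,
    gridded prediction over a 1-km population grid, and
    population-weighted exposure quartile misclassification between
    models.  A seeded synthetic-data generator emulates a 35-site
    monitoring network with spatially correlated covariates so the whole
    pipeline is testable without proprietary monitoring or GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    car,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
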