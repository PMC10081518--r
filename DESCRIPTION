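Package: plumefuse
Title: Hourly Wildfire PM2.5 Surfaces from Fused Monitor, Low-Cost Sensor,
    Satellite and Meteorology Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating hourly surface PM2.5 concentrations during
    wildfire smoke episodes by fusing regulatory-monitor measurements with
    calibrated low-cost sensor data, geostationary satellite aerosol products
    and high-resolution meteorology on a common modeling grid. Low-cost
    sensors are calibrated against collocated regulatory monitors with
    geographically weighted regression; ground values are deduplicated per
    grid cell; an inverse-distance-weighted neighbor layer is added as a
    predictor; rare high-concentration observations are oversampled with
    SMOTE inside cross-validation folds; and a weighted random forest is
    trained and evaluated with out-of-bag, spatial leave-group-out and
    temporal blocked cross-validation. A seeded synthetic-domain generator
    reproduces the statistical structure of a smoke episode (moving plume,
    sparse unbiased monitors, dense biased sensor clusters, informative
    satellite missingness) so the full pipeline can be exercised and
    validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    geosphere,
    ranger,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
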