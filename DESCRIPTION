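Package: vineflux
Title: Vineyard Leaf Area Index Estimation and Two-Source Energy Balance
    Evapotranspiration Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating grapevine leaf area index (LAI) from
    multispectral surface reflectance and for quantifying how LAI errors
    propagate through thermal-based evapotranspiration modelling.  Provides
    vegetation-index computation with Landsat-8 and Sentinel-2 band
    semantics (including the red-edge inflection point), a rule-based
    piecewise-linear regression (model tree) with hybrid area-fraction
    sample weighting and repeated k-fold plus leave-one-site-out
    cross-validation, a Priestley-Taylor two-source energy balance (TSEB-PT)
    solver that partitions latent heat into soil evaporation and canopy
    transpiration, an LAI-perturbation sensitivity experiment, and a
    synthetic vineyard-scene and forcing generator so the full pipeline runs
    without field data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
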