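Package: fluxrep
Title: Spatial Representativeness of Eddy-Covariance Flux Towers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assesses how well a single eddy-covariance flux tower represents
    the landscape around it. Computes half-hourly two-dimensional flux
    footprints from standard micrometeorological drivers, accumulates them
    into an annual cumulative footprint climatology with 50-80 percent
    source-area contours, overlays the climatology on categorical land-cover
    and NDVI rasters to obtain footprint-weighted cover fractions and
    vegetation statistics, estimates directional semivariograms with
    spherical-model fits as a heterogeneity measure, quantifies sensor
    location bias against contour- and window-defined target areas, and
    classifies each site into three representativeness levels. A synthetic
    scene generator (met series, patchy land cover, Gaussian random NDVI
    fields, lateral-wind-speed training data) provides statistically
    controlled inputs so the whole pipeline is testable without restricted
    tower or satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
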