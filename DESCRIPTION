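Package: forestcondition
Title: Quantile-Based Forest Condition Monitoring from Satellite Greenness Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computation chain for monitoring forest condition from 16-day
    composite NDVI raster time series. Conditions per-pixel NDVI series
    (quality masking, linear gap filling, Gaussian-filter outlier screening
    and smoothing, pixel-specific detrending), derives two relative
    greenness metrics per pixel and day of year across the observational
    record, a rank-based quantile Q centered on 0.5 and the proportional
    deviation from the median (PDM), classifies them on the standard break
    schemes, and summarises their spatial distribution as histograms.
    Includes growing-season masking from monthly temperature climatologies,
    multi-epoch forest-cover masking, the statistical procedures used to
    analyse disturbance hot spots (Wilcoxon rank-sum comparisons with
    compact letter displays, phenology regression, frost probability, gust
    binning), a synthetic scene generator with known ground truth, and a
    batch pipeline with a thin command-line wrapper.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
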