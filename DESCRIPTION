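Package: lspheno
Title: Land Surface Phenology from Multi-Index Vegetation Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting land surface phenology from multiband
    surface-reflectance time series. Computes the enhanced vegetation index
    (EVI), kernel NDVI (kNDVI) and plant phenology index (PPI) with
    quality-flag filtering, 8-day compositing and leading-gap climatological
    fill; reconstructs daily seasonal trajectories with a weighted harmonic
    rough fit and a Beck double-logistic fine fit under TIMESAT-style
    upper-envelope reweighting; extracts the five Gu-method transition dates
    (upturn, stabilization, initial downturn, plateau-adjusted downturn,
    recession) by tangent-line geometry; quantifies agreement of indices with
    solar-induced fluorescence and flux-tower gross primary productivity via
    per-pixel correlation and cross-validated regression; and maps
    interannual phenology trends with Theil-Sen slopes and Mann-Kendall
    significance. A synthetic-scene generator with known per-pixel
    phenological truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
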