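Package: scalesdm
Title: Interactive Scale Effects in Presence-Background Species Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the interactive effects of total study extent and
    raster grain size on presence-background species distribution models. Provides
    a lightweight planar raster engine (aggregation, bilinear resampling, slope,
    distance rasters, presence rasterization, PCA band reduction, ESRI ASCII grid
    I/O), a synthetic-landscape generator with known habitat truth and survey-style
    presence sampling, nested extent replication with background sampling and
    k-fold splits, a from-scratch L1-penalized maximum-entropy (Gibbs / IPP)
    presence-background model with permutation importance, response curves and
    presence-only AICc, threshold-optimized accuracy metrics (AUC, maximum TSS,
    point-biserial correlation), and a factorial experiment driver with
    cross-extent transfer evaluation, environmental-gradient and parsimony
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
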