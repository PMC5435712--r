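Package: wssmetrics
Title: Wall Shear Stress Metrics and Pulsatile Flow Models for Vessel Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of wall shear stress (WSS) vector time series on
    triangulated vessel surfaces: time-averaged WSS (TAWSS), oscillatory shear
    index (OSI), relative residence time (RRT), thresholded area-ratio and
    binned-area statistics, and regional summaries. Includes reduced-order
    pulsatile pipe-flow models (analytic Womersley solution and a
    Crank-Nicolson finite-difference solver), branch flow splitting and
    Reynolds-number reporting; a synthetic-data generator producing curved-arch
    vessel surfaces, rat-like cardiac waveforms, WSS fields with planted
    oscillatory structure and study tables with planted correlations; and a
    statistics stage (group summaries, ANOVA/Kruskal-Wallis, Pearson
    correlation with regression) with a deterministic end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
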