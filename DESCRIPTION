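Package: figround
Title: Figure-Ground Statistics of Natural Scene Motion and Distance in
    Simulated Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates natural scenes with figure/ground annotations and
    measures the motion and distance statistics that distinguish visual
    figures from their surroundings at the scale of middle-temporal (MT)
    receptive fields.  Provides a scene raster data model with
    standard-format I/O, a synthetic scene generator, motion-epoch
    selection from mean-speed time series, a gaze simulation (saliency
    median split, smooth pursuit, vergence and binocular disparity
    geometry), simulated receptive-field (sRF) sampling with acceptance
    rules, the figure-ground statistical analyses (circular statistics,
    t-tests, ANOVA with Tukey HSD, rank-sum, Rayleigh and Kuiper tests,
    probability-ratio curves with bootstrap confidence intervals), and a
    toy MT population model with bi-speed combination strategies and a
    response-weighted-average decoder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
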