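Package: foamquant
Title: Quantitative Imaging of Foam-Like Cellularization in Chytrid Sporangia
Version: 0.1.0
Authors@R:
    person("foamquant", "developers", email = "foamquant@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying foam-like (aphrogenic) cellularization from
    time-lapse fluorescence microscopy of chytrid sporangia. Provides ellipse
    fitting and concentric-ellipse geometry, polar unwrapping, Plateau
    vertex-angle metrology, nuclear segmentation and cortical nuclear ratio
    time series, daughter-cell size estimation from membrane intensity peaks,
    Haralick Angular Second Moment texture dynamics, particle image
    velocimetry with radial velocity decomposition for laser-ablation recoil
    analysis, kymographs and furrow-tip recoil curves, permutation and
    bootstrap resampling statistics, and a seeded synthetic-imaging generator
    that renders all scene types with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
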