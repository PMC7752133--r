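Package: poltirf
Title: Single-Complex Fluorophore Orientation Analysis for Polarized TIRF
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward modelling and quantification of fluorophore dipole
    orientation in single nuclear pore complexes imaged by polarized
    total internal reflection fluorescence microscopy (pol-TIRFM).
    Provides a Fresnel-based evanescent-field model with azimuthal beam
    scanning, a cos-squared dipole excitation law with analytic
    wobble-cone averaging, a rigid/flexible linker geometry model that
    maps alpha-helical linker length to dipole orientation, an
    acquisition-faithful synthetic image generator (alternating p/s
    frame stacks with Poisson shot noise, camera gain, read noise and
    offset), the automated punctum quantification pipeline (frame
    summing, camera-background subtraction, top-hat filtering,
    Laplacian-of-Gaussian detection, dual-polarization Gaussian-fit
    quality control, max-pixel p:s ratios), acceptor-photobleaching
    FRET efficiency quantification, and the condition-level statistics
    used to compare orientational states (quartile summaries, t-tests,
    one-way ANOVA with Tukey post hoc, spatial-uniformity and
    intensity-unimodality checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
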