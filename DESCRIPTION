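Package: cardiomapr
Title: Optical Mapping, Calcium Transient, Morphometry and Patch-Clamp
    Analysis for Stem-Cell-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-flavoured pipeline for the functional
    characterization of cardiomyocyte-like cells in culture: extraction of
    calcium-transient metrics (spontaneous excitation interval, CaT50,
    regularity class) from fluorescence movies, adaptive per-pixel-threshold
    activation-time mapping, a probabilistic frame-rate-censored lower bound
    on conduction velocity, cell morphometry (area, aspect ratio,
    circularity, box-counting fractal dimension, Feret diameter) with FFT
    detection of sarcomeric striation, and voltage/current-clamp sweep
    metrics (capacitance-normalised current densities, I-V curves, APD80).
    Ships a synthetic-data module that generates movies, traces, cell
    images and sweeps with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
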