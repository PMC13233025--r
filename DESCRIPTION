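Package: holovol
Title: Cell Volume Quantification from Off-Axis Digital Holographic
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free cell volume measurement by off-axis
    digital holographic microscopy. Simulates holograms of ground-truthed
    phase phantoms (microspheres, spherical caps, pancake-like cells with
    pseudopodia), reconstructs the complex object field by Fourier
    sideband demodulation and angular-spectrum propagation with
    frequency-energy autofocus, recovers continuous phase by
    quality-guided unwrapping with Zernike polynomial and median-filter
    background compensation, segments cells by dual-threshold
    morphological reconstruction, and quantifies optical volume, shape
    descriptors, and volume dynamics (dV/dt staging) over time series.
License: MIT + file LICENSE
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
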