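Package: endodance
Title: Quantitative Analysis of Endosome Dynamics in Growing Root Hairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed pipeline for quantifying early and late
    endosome dynamics in root hair time-lapse fluorescence microscopy:
    difference-of-Gaussians spot detection with sub-pixel localization,
    optimal-assignment particle tracking with path-length filtering,
    kymograph construction with steepest-slope speed estimation and
    continuous/discontinuous movement classification, detection of
    transient pairwise interactions (dancing endosomes) and sustained
    clustering/fusion events, FWHM-based size measurement on
    super-resolution-like frames, and root-hair zone analysis. Includes a
    ground-truthed synthetic movie generator (spinning-disc and SIM-like
    modalities) so every stage of the analysis is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stats,
    graphics,
    utils,
    ggplot2,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
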