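Package: flimscreen
Title: High-Content FLIM-FRET Plate Screening with Time-Gated Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multiwell-plate screens of protein-protein
    interactions read out by Förster resonance energy transfer (FRET) and
    wide-field time-gated fluorescence lifetime imaging (FLIM). Provides a
    forward model for gated detection of exponential decays (instrument
    response convolution, repetition-rate wrap-around, time-varying
    background), per-cell monoexponential lifetime fitting, global
    double-exponential fitting by variable projection with a shared quenched
    lifetime, intensity-threshold cell segmentation, significance-threshold
    interaction calling, fluorophore intensity calibration, and per-cell
    dissociation-constant estimation from FRET population fractions. A
    ground-truthed synthetic plate generator emulates gated acquisition of
    co-transfected cells for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
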