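Package: gedipipe
Title: Single-Cell Death Detection from Ratiometric Biosensor Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for genetically encoded death indicator (GEDI)
    time-lapse microscopy of neurons. Renders synthetic two-channel plates with
    known ground truth, processes image series (median background subtraction,
    montage stitching, translational registration, soma segmentation, feature
    extraction), links somata into single-neuron tracks by centroid proximity,
    calibrates the GEDI-ratio death threshold from live and dead reference
    populations, assigns per-neuron times of death or censoring, and summarises
    cohorts with Kaplan-Meier, cumulative risk-of-death and Cox proportional
    hazards statistics, plus post-death fluorescence decay and signal-rise
    kinetics fitting and equilibrium Hill-model curves for calcium indicators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    survival,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
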