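Package: poromech
Title: Pore Morphometry, Compression Mechanics and Acoustic Emission for
    Demineralized Bone Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of fatigue effects on demineralized
    cortical bone matrix. Implements an illumination-corrected
    fixed-threshold segmentation protocol for confocal microscopy images,
    per-pore geometric descriptors (area, elongation, circularity, shape
    roughness) with histogram and pore-fraction summaries, compression
    descriptors (stress, strain, work to failure, bending-fatigue secant
    moduli), acoustic-emission hit detection with binned and cumulative
    energies, and the group-comparison statistics (paired t, two-way
    ANOVA with Tukey post hoc). A synthetic-data module generates
    calibrated images, force-deformation curves and AE waveforms with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
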