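Package: flagkin
Title: Flagellar Waveform Kinematics and Energetics for Tethered Sperm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of planar flagellar beating in head-tethered sperm
    recorded by high-speed dark-field microscopy. Provides a synthetic
    beat-and-video generator with ground truth, centerline tracing from
    image stacks, tangent-angle waveform and curvature-kymograph
    construction, beat-frequency and per-section amplitude estimation,
    midpiece flexibility classification, shape-mode (principal component)
    decomposition of the beat, resistive-force-theory energetics with a
    sliding-filament active-moment recovery, and per-animal group
    statistics for population comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    signal
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
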