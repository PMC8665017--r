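Package: fcmap
Title: Functional Connectivity Mapping from Optogenetic Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for mapping functional connectivity between
    Drosophila leg proprioceptor subtypes and second-order ventral nerve
    cord neurons from two-photon calcium imaging movies recorded during
    optogenetic stimulation. Implements delta-F-over-F extraction with a
    sliding lowest-window baseline, response kinetics (peak, time to 50%
    of peak, half-decay time) and an adaptation index, construction of
    pre-subtype by post-class connectivity matrices with two-stage
    (within-fly, then across-fly) averaging, vibration tuning curves, and
    joint-angle tracking of a pin-marked tibia via image-moment ellipse
    orientation. A seeded synthetic-data generator emulates the stimuli
    and signals (GCaMP-like transients under escalating light pulses,
    sinusoidal tibia vibration, rendered leg videos) so the whole
    pipeline is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
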