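Package: ca1drift
Title: Multi-Day Place-Cell Classification and Silent-Cell Tracking for
    Virtual-Corridor Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chronic two-photon calcium imaging of
    hippocampal CA1 pyramidal cells during navigation in a virtual linear
    corridor. Filters deconvolved event trains against local and global
    fluorescence noise estimates, classifies cells per session as silent,
    active non-place or place cells using an odd-even reliability gate and
    circular-shuffle spatial-information tests, delineates place fields by
    peak prominence, matches activity-based to anatomy-based ROI
    segmentations, registers and links cell identities across days, tracks
    persistent silence against a Markov unsilencing model, extracts
    intrinsic electrophysiological properties from current-clamp sweeps,
    and ships a synthetic-data generator with known ground truth so every
    stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
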