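Package: casync
Title: Developmental Desynchronization Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal two-photon calcium imaging of
    developing cortex. Implements quietest-period modified Z-scores, calcium
    activity epoch detection, an epoch-scramble bootstrap classifier of
    stimulus-responsive neurons, pairwise-correlation measures of network
    synchrony on deconvolved traces, and the accompanying rank-based group
    statistics (Friedman omnibus with Bonferroni-adjusted post-hoc tests,
    unpaired rank bootstrap). A synthetic-data module simulates GCaMP6s
    recordings with ground truth (spike trains, fluorescence traces, rendered
    movies with rigid drift) so every stage of the pipeline can be validated
    without access to raw experimental data. Includes rigid movie
    registration, ROI trace extraction, delta-F-over-F normalization, and an
    optical intrinsic signal response-map rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
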