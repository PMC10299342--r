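Package: graftsync
Title: Graft-Host Electromechanical Coupling Analysis for Cardiac Optical Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to decide whether cardiomyocyte grafts on a beating heart fire
    synchronously with host systole from calcium-sensitive optical-mapping videos.
    Implements motion-compensated region-of-interest tracking with the
    brightest-pixel frame-shift rule, calcium trace extraction with dF/dF_max
    normalization, systole/diastole segmentation from the normalized inter-frame
    difference signal, spontaneous-rate estimation, and control-anchored
    classification of 20-frame systolic windows by principal component analysis
    with a Mahalanobis gate. Includes a synthetic optical-mapping video generator
    with full ground truth (beating-tissue background, advected graft blobs,
    calibrated noise) emulating Langendorff, culture-dish, and in vivo recording
    regimes, plus readers and writers for multi-page TIFF stacks and the
    pipeline's CSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
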