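Package: cdkd
Title: Heartbeat Keyframe Detection for Coronary Angiography Image
    Sequences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Locates heartbeat keyframes (frames at maximal vasodilation
    or vasoconstriction) in coronary digital subtraction angiography
    (DSA) image sequences. Each frame is mapped to a feature vector by a
    pluggable embedding backend, an all-pairs inter-frame similarity (or
    difference) matrix is built, windowed local extrema of the matrix
    name candidate frame pairs, and a greedy non-extremum suppression
    pass emits the final keyframe set. Ships the standard pixel-domain
    comparators (L1, PSNR, single-window SSIM), a per-frame evaluation
    protocol (accuracy, precision, recall with optional frame
    tolerance), a synthetic pulsating-vessel phantom generator with
    known ground-truth keyframes for end-to-end validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
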