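Package: lmtb
Title: Lightweight Multi-Scale Tea Bud Detector Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds and audits YOLO-LMTB, a lightweight one-stage detector for
    multi-scale tea-bud detection, alongside the unmodified nano baseline it
    derives from. Implements the three bespoke blocks -- a multi-scale
    edge-refinement context aggregator (MERCA) for the backbone, a dynamic-tanh
    token-statistics transformer (DHTST) replacing the attention stage, and a
    weighted bidirectional feature-pyramid neck with stride-4 detail injection
    -- on a small tape-based autodiff core, so forward passes, gradient flow
    and short CPU training runs work without an external deep-learning
    framework. Ships exact trainable-parameter and FLOP auditing, IoU-matched
    precision/recall and mean average precision, YOLO-format label reading and
    writing, mosaic augmentation, and a seeded synthetic tea-scene generator
    emulating dense, low-contrast, occluded bud targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    yaml,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
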