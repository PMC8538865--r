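Package: mrslots
Title: Explainable Image Classification with Multi-Resolution Slot Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an explainable convolutional image classifier built on
    iterative slot attention applied at several feature-pyramid levels. One slot
    is learned per class; sigmoid class-evidence maps from every level are
    combined by a saliency-weighted fusion rule into a single attention map at
    input resolution, and training couples a cross-entropy term on the deepest
    level's slot masses with an area regularizer that controls how much of the
    image the explanation may cover. Positive and negative explanation modes,
    a synthetic single-plant image generator with ground-truth masks, training
    via a built-in reverse-mode gradient tape with AdamW, and evaluation tools
    (confusion and attention-confusion matrices, localization enrichment,
    alpha-channel overlays, per-level map galleries) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
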