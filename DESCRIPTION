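Package: sossr
Title: Occlusion Segmentation by Soft-Voting Fusion of Semantic and Class-Agnostic Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining coarse semantic occlusion segmentations with
    fine-grained class-agnostic segment proposals, as produced by promptable
    foundation segmenters. Implements confidence-based soft voting that
    assigns one semantic class per segment proposal (the SOSS fusion),
    quality filters for segment stacks, pixel-wise evaluation metrics
    (accuracy, precision, recall, F1, IoU, ROC-AUC) scoped to a region of
    interest, polygon-annotation rasterization with ROI crop/pad
    preprocessing, paired image and mask augmentations including a
    copy-paste transform, and a seeded synthetic-scene generator so the
    whole pipeline is testable without clinical image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
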