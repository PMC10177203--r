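Package: histocad
Title: Computer-Aided Classification of H&E Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided pathology pipeline for binary (benign versus
    malignant) classification of hematoxylin-and-eosin histology images.
    Frozen convolutional backbones tap intermediate feature maps, pool them
    globally and concatenate them into image descriptors; kernel support
    vector machines (with a Nystroem low-rank approximation) or stochastic
    gradient boosting classify the descriptors under patient-grouped nested
    cross-validation with random-search tuning and center-crop or ten-crop
    majority-vote testing. Includes readers for case-structured image
    archives, two training augmentation strategies, and a synthetic H&E
    texture generator so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
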