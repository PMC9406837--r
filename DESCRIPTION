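Package: histofusion
Title: Hybrid Deep and Handcrafted Feature Fusion for Histopathology Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline-testable pipeline for two-class (normal vs malignant)
    classification of H&E-stained tissue-slide images. Implements gray-world
    colour normalisation with Gaussian/Laplacian enhancement, a stratified
    80/20-within-80/20 split with a deterministic 12-variant training-set
    augmentation, deep feature extraction through seeded test backbones (with
    an adapter contract for pretrained networks), four handcrafted descriptor
    blocks (Haar wavelet subband statistics, a 24-bit 5x5 local binary pattern
    histogram, a fuzzy colour histogram over hue, and direction-averaged
    Haralick co-occurrence statistics), PCA reduction of deep features and
    fusion with the handcrafted block, and two classifier heads (a linear SVM
    and a small feed-forward network with validation-based early stopping),
    evaluated by a confusion-matrix metric panel, ROC AUC and an error
    histogram. A seeded synthetic two-class image generator makes every stage
    runnable with no external data.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    pROC,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
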