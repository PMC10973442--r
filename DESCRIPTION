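Package: bcicm
Title: Unsupervised Classification of Breast-Tumor Histopathology Images via
    Texture Features and Dynamic Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Separates unlabeled histopathology-style images into two classes
    without training labels. Images are reduced to multiscale gray-level
    co-occurrence matrix (GLCM) texture features (energy, contrast, inverse
    difference moment, correlation, plus optional entropy and Tamura
    coarseness), and the feature vectors are clustered by an unsupervised
    dynamic learning mechanism: a particle population in which each particle
    encodes two cluster centers and improves by Gaussian pairwise learning
    toward better neighbors and the global best, minimizing the sum of
    nearest-center distances. Includes the full evaluation protocol (confusion
    matrix, accuracy, sensitivity, precision, specificity, F1, ROC/AUC,
    cluster-to-class alignment), supervised random-forest and SVM baselines,
    a resolution sweep, and seeded synthetic-data generators for two-class
    textures and feature-space blobs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    randomForest,
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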