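Package: randnn
Title: Randomized Neural Network Classifiers on Deep Image Features
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form randomized neural-network classification heads
    (Schmidt networks, extreme learning machines, and random vector
    functional link networks) trained by Moore-Penrose pseudo-inverse on
    features extracted from a convolutional backbone, together with a
    stratified five-fold cross-validation protocol, confusion-matrix
    metrics (accuracy, sensitivity, specificity, precision, F1), ROC/AUC,
    Grad-CAM attention maps, a seeded synthetic image and feature
    generator for two-class medical-imaging style data, and a command
    line interface tying the stages into a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
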