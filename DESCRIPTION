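Package: pvcmetric
Title: Premature Ventricular Contraction Detection by Deep Metric Learning and KNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects premature ventricular contractions (PVCs) in single-lead
    ambulatory electrocardiograms. Heartbeats are extracted as fixed-length
    windows centred on annotated R-peaks, embedded into a low-dimensional
    feature space by a 1-D convolutional metric-embedding network trained
    with a cosine-similarity triplet margin loss and a multi-similarity pair
    miner, and classified by a k-nearest-neighbour vote over the learned
    embeddings. Includes a synthetic ECG generator with controllable
    normal/PVC morphology and rhythm patterns (bigeminy, trigeminy,
    compensatory pauses), optional denoising operators (FIR notch filters,
    two-stage median baseline removal), the standard five evaluation metrics
    derived from the confusion matrix, and sweep harnesses over feature
    count, pooling type, loss margin and K.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
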