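Package: affdecode
Title: Layerwise Decoding of Visually Evoked Affect with Noise-Ceiling
    Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking how well hierarchical feature spaces
    (for example, the layerwise activations of deep vision networks) linearly
    predict group-average human affect ratings of images. Implements
    inter-rater variability ceilings (mean-minus-one correlation and
    Spearman-Brown corrected split-half reliability), sparse random projection
    with the Johnson-Lindenstrauss minimum-dimension bound, closed-form
    leave-one-out cross-validated ridge decoding, noise-corrected "explainable
    variance explained" scoring with best-layer and layer-depth analyses, and
    an inferential suite (respondent-pool bootstraps with model rank
    tabulation, paired t tests with Holm correction and Hedge's g,
    Mann-Whitney comparisons, individual-respondent decoding, and
    cross-decoding between image sets). A synthetic-data generator produces
    rater pools and feature hierarchies with known ground truth so every
    stage is testable by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
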