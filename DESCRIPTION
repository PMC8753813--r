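Package: oaensemble
Title: Taguchi Orthogonal-Array Hyperparameter Screening and
    Majority-Vote Ensembles for Binary Cell-Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening classifier training hyperparameters with a
    three-level L9(3^4) Taguchi orthogonal array and for evaluating
    majority-voting classifier ensembles on binary microscopy-image tasks
    such as distinguishing acute lymphoblastic leukemia (ALL) blast cells
    from normal lymphocytes.  Implements the smaller-the-better
    signal-to-noise ratio, factor response tables with best-level inference,
    Taguchi ANOVA with percentage contributions, confusion-matrix metrics
    (accuracy, precision, recall, specificity, F1), per-image ensemble error
    profiles, a synthetic two-class cell-image generator with tunable
    separability, and two reference trainer backends (a deterministic
    surrogate objective and a small trainable convolutional classifier) so
    the whole workflow runs at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
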