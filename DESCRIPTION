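Package: xmvpa
Title: Explainable Multivariate Pattern Analysis for fNIRS Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Decodes binary stimulus conditions from trial-wise functional
    near-infrared spectroscopy (fNIRS) channel features using an interval
    type-2 fuzzy rule-based classifier.  Linguistic patterns of the form
    "IF channel activity is <label> ... THEN stimulus is <class>" are learned
    jointly with the numeric ranges of the conceptual labels (inactive,
    active, very active) by a genetic algorithm that minimises one minus the
    mean k-fold cross-validated Matthews correlation coefficient.  Includes
    window-mean feature extraction from epoched time series, dominance-score
    rule fitting, permutation-baseline significance testing, a synthetic data
    generator with planted rules for end-to-end validation, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
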