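Package: tcmrx
Title: Transformer-Based Herbal Prescription Recommendation from Inpatient Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recommends traditional Chinese medicine (TCM) prescriptions for
    inpatients from structured electronic health records. Patient charts are
    converted into chronologically ordered token sequences, embedded with
    skip-gram word vectors, and classified by a two-encoder transformer with a
    sigmoid multilabel head over first-category medicines. An LSTM-based
    generative adversarial network produces one noise-added copy of every
    training embedding, doubling the training set to counter overfitting.
    Predicted and physician-authored prescriptions are compared after rolling
    both up to parent drug categories, since two different herbs under the
    same first category are clinically interchangeable. Includes a synthetic
    cohort generator (latent syndromes emitting symptoms and labs over time,
    with within-category drug substitution) standing in for proprietary
    hospital corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
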