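Package: clinsbd
Title: Sentence Boundary Disambiguation for Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sentence boundary disambiguation (SBD) for clinical free text,
    framed as B/I/O token tagging. Implements a character-level convolutional
    enrichment of word vectors feeding a bidirectional LSTM tagger with a
    sigmoid prediction layer, class-weighted binary cross-entropy training
    with early stopping, and three domain-adaptation strategies (merged
    training, continued training, and a stacking ensemble that sums the
    contextual representations of a frozen source-domain network and a
    trainable target-domain network). Includes BRAT standoff corpus reading
    and writing, span-to-tag conversion, corpus statistics and inter-annotator
    agreement, a logistic-regression character-window baseline, tag-level
    evaluation with O-exclusion, and a synthetic clinical-note generator with
    two configurable domains so the full pipeline can be exercised without
    access to protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
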