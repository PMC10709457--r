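Package: mgner
Title: Dictionary Matching-Graph Neural Tagger for Biomedical Named
    Entity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Named entity recognition for biomedical text with an entity
    dictionary used as a matching graph rather than a masked feature.
    Every dictionary match in a sentence becomes a directed edge from its
    first to its last token; a bidirectional graph convolutional network
    encodes the forward and reversed adjacency on top of a bidirectional
    LSTM sentence encoder, and tokens are classified into BIOES tags.
    Includes exact-match entity P/R/F1 scoring, CoNLL and dictionary file
    readers, a seeded synthetic-corpus generator exhibiting overlapping
    and nested dictionary matches, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
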