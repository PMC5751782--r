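Package: mcnn
Title: Multiple-Label Convolutional Neural Network for Disease Named
    Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A window-based convolutional sequence tagger for disease
    named entity recognition in biomedical abstracts. Instead of a CRF
    decoding layer, training uses a multiple label strategy (MLS): an
    auxiliary softmax predicts the previous and next tokens' labels
    alongside the centre token's, capturing label correlations through
    the output layer alone. The package covers the full pipeline:
    tokenization with number normalization, PubTator-style corpus
    reading and BIO projection, MEDIC-style lexicon feature tagging,
    character-level CNN word representations, the pooling-free stacked
    convolutional network with hand-written backpropagation and SGD,
    ill-legal BIO sequence repair, Schwartz-Hearst abbreviation
    propagation, exact-span mention-level evaluation, and a seeded
    synthetic corpus generator so the whole system is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
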