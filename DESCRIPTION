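Package: dnerlink
Title: Disease Named-Entity Recognition and Concept Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for recognizing disease mentions in PubMed-style
    titles and abstracts and linking them to controlled-vocabulary concept
    identifiers. Two base taggers are provided: a feature-rich linear-chain
    conditional random field over BIO labels with rule-based post-processing
    (repeated-entity propagation and Schwartz-Hearst abbreviation
    resolution), and a bidirectional recurrent neural network over word
    embeddings trained with Adam and dropout. An SVM meta-classifier fuses
    the per-token outputs of the two taggers. Recognized mentions are
    normalized to concept identifiers by TF-IDF cosine ranking over
    synonym-expanded concept documents. Includes a PubTator-format reader
    and writer, a seeded synthetic corpus generator, mention-level and
    concept-level evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
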