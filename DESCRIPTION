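Package: hroc
Title: Proximity-Weighted Rocchio Pseudo-Relevance Feedback Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pseudo-relevance-feedback (PRF) retrieval with
    Hyperspace-Analogue-to-Language (HAL) term-proximity weighting of
    expansion terms. Implements Porter-stemmed tokenization and positional
    inverted indexing, Okapi BM25 and Dirichlet-smoothed language-model
    first-pass retrieval, classic Rocchio expansion, the HRoc family of
    proximity-weighted expansion models with three score normalizations and
    adaptive sliding-window sizing, TREC-style evaluation (MAP, P@k, F1,
    parity-based two-fold cross-validation, grid sweeps), readers and writers
    for TREC topics, qrels and run files, and a deterministic synthetic
    collection generator with controlled proximity structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
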