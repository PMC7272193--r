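Package: lettercode
Title: Compositional Letter Codes for Visual Search and Word Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling letter strings as compositional neural codes.
    Builds artificial letter-tuned neurons by multidimensional scaling of
    visual-search dissimilarities (reciprocal reaction times), predicts
    string-string dissimilarities as weighted sums of single-letter responses,
    fits spatial summation weights by multi-start least squares, provides a
    linear part-sum alternative, models lexical-decision reaction times from
    word frequency and distance-to-nearest-word (with an orthographic
    Levenshtein distance baseline and cross-validated bootstrap model
    comparison), and offers representational-similarity statistics
    (cross-validated Mahalanobis distances, cosine semantic dissimilarity,
    bootstrap RSA and partial correlations). A synthetic-data generator
    reproduces the statistical structure of oddball-search and
    lexical-decision studies so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
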