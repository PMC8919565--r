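Package: famtrio
Title: Ensemble Protein Family Classification from Homology Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-family ensemble classification of protein sequences in the
    twilight zone of sequence similarity. For every protein family, three
    weighted linear support-vector classifiers (squared hinge loss) are
    trained on similarity and dissimilarity features derived from local
    alignment against a small per-family reference database (bit-score,
    E-value, percent identity) and from position-specific profile scores
    (bit-score, E-value). Predictions are combined by majority vote with a
    closed-form ensemble probability. Includes a synthetic family generator
    with controllable divergence so twilight-zone (<= 40 percent identity)
    behaviour, novel-family rejection and identity-binned accuracy can be
    evaluated without external databases, plus parsers for BLAST tabular and
    HMMER domain-table output so precomputed homology searches can be used
    instead of the built-in scorers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
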