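Package: predlattice
Title: Time-Resolved Encoding Models and Stimulus-Dependency Controls for
    Word-Locked Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for word-locked, time-resolved encoding analyses of
    continuous recordings during naturalistic listening. Builds sliding-window
    epoch lattices around word onsets, fits per-unit per-timepoint
    cross-validated ridge encoding models from word embeddings, and evaluates
    the resulting correlation curves with sign-flip cluster permutation tests
    using threshold-free cluster enhancement. Includes passive control
    analyses (embedding self-predictability and word-level speech acoustics),
    dependency-correction procedures (first-occurrence bigram filtering and
    ordinary-least-squares residualisation of neighbouring embeddings), and a
    fully seeded synthetic-data generator with Markov word sequences,
    structured or arbitrary embeddings, linear neural mixtures with an
    optional ground-truth pre-activation term, and word-specific audio
    signatures, so that pre-onset encoding effects can be studied under known
    stimulus dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
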