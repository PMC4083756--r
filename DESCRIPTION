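Package: pathmm
Title: Disease-Specific Ranking of Missense Variants with Profile Hidden
    Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks non-synonymous single nucleotide variants (missense
    substitutions) by combining position-specific conservation from profile
    hidden Markov models with pathogenicity weights estimated from labelled
    training mutations, in the style of the FATHMM family of algorithms.
    Supports a disease-specific weighting scheme over 17 root disease
    concepts in which mutations causing other diseases are treated as
    neutral, leave-one-out weight adjustment, class-normalized
    confusion-matrix statistics, ROC/AUC analysis, protein-level k-fold
    cross-validation, and a seeded synthetic-data generator (HMMER3 ASCII
    profiles, domain annotations and concept-labelled variant sets) for
    fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite
Config/testthat/edition: 3
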