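Package: enhancerf
Title: Random-Forest Prediction of Tissue-Specific Enhancers from k-mer
    and Chromatin-Signal Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates random-forest classifiers that predict
    tissue-specific enhancer activity from canonical k-mer frequencies and
    mean histone-modification signal, builds matched random negative sets
    with negative-binomial length sampling, selects all-relevant features
    with a shadow-feature (Boruta-style) procedure, scores whole genomes in
    overlapping windows, diagnoses promoter bias of the resulting
    predictions against transcription start sites and DNase-hypersensitive
    sites, and corrects that bias with a two-step classifier that multiplies
    an enhancer-versus-random score by a random-versus-promoter score. A
    seedable synthetic-genome generator with planted enhancer and promoter
    elements makes the full pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    S4Vectors,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
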