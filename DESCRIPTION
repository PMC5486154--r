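Package: ctleeg
Title: Conditional Transfer Learning for EEG-Based Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Subject-to-subject conditional transfer learning (cTL) for two-class
    EEG emotion classification (valence and arousal). Extracts differential
    laterality (DLAT) band-power asymmetry features via a short-time Fourier
    transform with gain-model baseline calibration, weights features with a
    from-scratch two-class ReliefF, classifies with Gaussian naive Bayes, and
    gates transfer per target subject by chance-level default accuracy before
    borrowing labeled trials from the most similar source subjects (Pearson
    correlation of ReliefF weight vectors). Includes leave-trial-out validation
    with class-balanced feature-count optimization, default/rTL/cTL/oTL scenario
    benchmarks, source-count sweeps, and a synthetic multi-subject EEG cohort
    generator with controllable engagement and inter-subject signature
    similarity. All analysis results are tibbles with broom-style tidiers and
    ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
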