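Package: emotqwt
Title: Five-Class EEG Emotion Recognition via Tunable Q-Factor Wavelets
    and Binary Grey Wolf Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for recognising five emotional states
    (happy, anger, sad, relax, neutral) from 32-channel scalp EEG rated on
    the valence-arousal plane. Provides DEAP-layout input and preprocessing
    (4-45 Hz zero-phase band-pass, common average reference), a tunable
    Q-factor wavelet transform (TQWT) implemented as an exact Parseval
    tight frame, five per-sub-band time-domain and non-linear features
    (sample entropy, signed second-order difference mean and its normalized
    variant, Hjorth mobility and complexity), wrapper feature selection by
    the binary grey wolf optimizer (BGWO2), one-vs-rest RBF-SVM
    classification under stratified 6-fold cross-validation with accuracy,
    macro sensitivity/specificity and a chance-corrected kappa, and a
    seeded synthetic-cohort generator with class-conditioned band-power
    structure so the whole pipeline runs without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
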