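Package: cryregimes
Title: Regime-Segmented Acoustics and Perceptual Analysis of Infant Vocal Distress
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for characterizing infant vocalizations along the
    wail-whine-vocant distress continuum. Provides readers and writers for
    mono WAV audio, Praat TextGrid / TSV vibratory-regime tiers and
    listener-rating tables; per-utterance acoustic profiling (duration,
    pitch, peak RMS, long-term average spectrum, spectral ratio and
    concentration, cepstral peak prominence) with regime-wise aggregation;
    rater-panel agreement and coefficient-of-variation analytics;
    backward-AIC linear modeling of distress ratings; per-listener trend
    (Cox-Stuart), prevalence and permutation statistics of acoustic-cue use;
    and a synthetic-data module pairing a source-filter utterance
    synthesizer (with scheduled vibratory-regime events and ground-truth
    tiers) with a rater-panel simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
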