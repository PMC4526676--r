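Package: ultracoll
Title: Auditory Pathway Responses to Mouse Ultrasonic Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how stations of the ascending auditory
    pathway (auditory nerve, dorsal cochlear nucleus, central nucleus of the
    inferior colliculus) respond to high-ultrasonic mouse vocalizations.
    Implements extracellular preprocessing (band-pass filtering, spike-snippet
    extraction, analog multi-unit activity envelopes), spike sorting with
    PCA projection, Gaussian-mixture clustering and isolation-distance
    quality gating, per-unit response statistics (PSTH, interspike-interval
    CV, first-spike latency, PSTH shape classes), frequency-response-area
    construction with characteristic-frequency and F-max estimation,
    vocalization responsiveness testing (Wilcoxon rank-sum on driven versus
    spontaneous counts, PSTH signal-to-noise ratio), auditory brainstem
    response wave I/V quantification with objective thresholds, and
    population summaries with bootstrap confidence intervals. A synthetic
    data generator produces tone pips, frequency-modulated ultrasonic calls,
    renewal-process spike trains, extracellular voltage traces and ABR sweep
    sets with known ground truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mclust,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
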