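Package: sleeparch
Title: Sleep Architecture and State-Conditioned EEG Spectral Analysis for
    Rodent Telemetry Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing scored rodent sleep recordings: hypnogram
    rescoring rules for REM-sleep scoring artifacts, bout detection and
    sleep-architecture summaries by zeitgeber hour and light/dark phase,
    per-epoch FFT power spectra with transition-epoch exclusion, band powers
    and band ratios, slow-wave-activity rebound analysis after sleep
    deprivation, murine Multiple Sleep Latency Test scoring, factorial
    group statistics (two-way and repeated-measures ANOVA, Fisher's LSD,
    Holm-Sidak per-bin comparisons), and a semi-Markov synthetic-cohort
    generator with known ground truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
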