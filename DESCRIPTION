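Package: fastkit
Title: Processing of Long EEG-fMRI and Sleep EEG Recordings
Version: 0.1.0
Authors@R: person("fastkit", "developers", role = c("aut", "cre"),
    email = "fastkit@example.org")
Description: Tools for manipulating long continuous multichannel EEG
    recordings with windowed (memory-mapped style) data access, importing
    BrainVision files by header translation, removing fMRI-induced gradient
    artefacts by averaged artefact subtraction (AAS), removing the cardiac
    pulse artefact (ballistocardiogram) by Gaussian-mean averaging, optimal
    basis set (OBS) PCA or a combined low/high-band method, sleep-score data
    structures with hypnogram statistics, score-aware Welch spectrograms with
    absolute, relative and deep-sleep-normalized band power, and
    spatiotemporal slow-wave detection with scalp trajectory extraction.
    Includes synthetic-data generators with known ground truth and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
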