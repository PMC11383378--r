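Package: psiacx
Title: Auditory Cortex Two-Photon, Widefield and Behavioral Analysis for
    Psychedelic Dosing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for studies of psychedelic drug
    effects on mouse auditory cortex and behavior. Processes registered
    two-photon calcium imaging movies into neuropil-corrected,
    quality-filtered, sigma-normalized dF/F trial rasters and 1-s response
    amplitudes; computes pure-tone frequency tuning curves, best frequencies,
    off-best-frequency selectivity and pairwise noise correlations; derives
    pixel-wise tonotopic maps from widefield movies via homomorphic
    illumination filtering and the dF/F90 criterion; quantifies free-roaming
    movement from video by frame differencing and Hilbert-envelope smoothing;
    and compares conditions with a pooled bootstrap test on the absolute
    difference of means. Ships seeded synthetic-data generators with embedded
    ground truth (tone protocols, GCaMP6s-like evoked transients with shared
    trial noise, tonotopic gradient movies, arena videos with programmed
    hypoactivity and head-twitch events) so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
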