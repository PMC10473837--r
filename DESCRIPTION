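Package: dynagaze
Title: Eye-Movement Dynamics During Dynamic Gaze Following
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing observer eye movements while following a
    gazer's head movement in short videos: saccade detection from 1000 Hz eye
    traces using velocity/acceleration thresholds, forward and reverse (return)
    saccade classification against the gazer goal vector, per-frame gazer
    head-feature extraction (vector distance, angular displacement, velocity,
    acceleration), event-aligned resampling statistics (participant bootstrap,
    cluster-based sign-flip permutation, BH-FDR, 2x2 repeated-measures ANOVA,
    power planning), and leave-one-movie-out kernel classification of which
    movies evoke frequent reverse saccades. Includes a synthetic-trial
    generator that emulates the study design (1.2 s videos at 30 fps,
    gaze-contingent freeze/erase manipulations) so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
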