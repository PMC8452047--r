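Package: uedyn
Title: Utterance Emotion Dynamics from Dialogue Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for utterance emotion dynamics (UED): lexicon-based
    valence-arousal trajectories of individual speakers in turn-structured
    dialogue, home bases (one-dimensional confidence bands and two-dimensional
    covariance confidence ellipses), emotional variability, displacement
    detection with peak distance and rise/recovery rates, emotion word
    density, pairwise speaker discordance over normalized narrative time,
    and penalized-spline trend curves with extremum location. Includes
    readers for dimensional (valence-arousal-dominance) and categorical
    word-emotion lexicons in the common tab-separated dialects, a
    turn-structured transcript reader, and a synthetic narrative generator
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
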