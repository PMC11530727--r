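Package: moodfuse
Title: Macro-Micro Multimodal Multitask Modelling of Daily Mood from
    Actigraphy and Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Personalized daily mental-health monitoring from ecological
    momentary assessment (EMA) records that pair wrist actigraphy (zero
    crossing mode and proportional integration mode windows) and speech
    embeddings with nine self-rated mood dimensions. Implements
    uncertainty-weighted (dynamic restrained uncertainty weighting, DRUW)
    fusion of the two modalities, a shared macro emotional space built from
    feed-forward and transformer-encoder layers, per-participant micro
    personalization layers, a DRUW multitask objective over the nine mood
    dimensions, concordance-correlation-coefficient evaluation, mixed-model
    within-individual validation, and a synthetic EMA simulator with exported
    ground truth so the whole pipeline can be exercised and tested without
    access to any private study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
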