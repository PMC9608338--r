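Package: abilikey
Title: Ability-Based Personalization of Single-Input Keyboards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes a user's two-dimensional cursor control as
    direction-specific Fitts' law constants from a multidirectional
    point-select task on a hexagonal honeycomb grid, then generates a
    personalized single-input keyboard layout by solving a quadratic
    assignment problem whose flow is letter-digraph frequency and whose
    distance is predicted movement time (Fast Approximate QAP solver).
    Includes a synthetic-user simulator for testing the full pipeline
    without human data, and communication metrics (accuracy, words per
    minute, Wolpaw information transfer rate, Fitts-digraph energy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
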