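Package: gazejoint
Title: Gaze-Contingent Joint Attention Battery Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, hardware-independent engine for gaze-contingent joint
    attention experiments of the kind used in screen-based eye-tracking
    research with autistic children. Provides declarative trial and phase
    definitions, dispersion-threshold (I-DT) fixation detection, a
    fixation/gaze-alternation trigger state machine with timeouts and manual
    overrides, a 32-stimulus counterbalanced battery builder covering
    responding to joint attention (RJA) and initiating joint attention (IJA,
    request and comment/reference) tasks, per-trial outcome scoring that
    separates participant-driven triggers from timeouts and overrides, and a
    parameterised synthetic gaze-stream simulator so every component can be
    tested at desk scale without eye-tracking hardware.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
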