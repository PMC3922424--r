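Package: hemiflip
Title: Flip-Based Hemispheric Lateralization of Resting-State Functional
    Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for hemispheric lateralization of resting-state
    functional connectivity. Computes a flip-based lateralization index
    (unflipped minus midsagittally flipped Fisher-z connectivity) over a set
    of cortical lateralization hubs, with BOLD confound regression, bandpass
    filtering, motion scrubbing (framewise displacement and DVARS),
    connection-level group statistics under configurable subject inclusion
    criteria, Benjamini-Hochberg false discovery rate control, and symptom
    severity correlations. Includes a synthetic BOLD cohort generator with
    injectable lateralization effects so the whole pipeline is testable
    without real imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
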