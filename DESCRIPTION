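Package: gridtrack
Title: Grid Cell Coding-Scheme Analysis on Circular Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of medial entorhinal cortex grid cell firing recorded
    while animals forage on a 1D circular track. Distinguishes four candidate
    distance-coding schemes (allocentric distance, path-integrated distance,
    travelled distance, elapsed time) through lap-correlation analysis with
    field-distance correction, 1D autocorrelation regularity tested against
    spike-time jitter surrogates, a three-parameter Gaussian spike-train model
    fitted by differential evolution, and a spectral one-peakness test against
    slices of a 2D hexagonal lattice. Includes 2D rate maps, gridness scoring
    with rotation shuffles, field spacing, head-direction and speed tuning,
    LFP theta analysis, cue-card visibility geometry, and a synthetic session
    generator with stored ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    graphics,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
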