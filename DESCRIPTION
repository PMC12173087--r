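Package: crowdtrack
Title: Continuous Psychophysics of Visual Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a continuous target-tracking paradigm
    for measuring the spatial extent and temporal dynamics of visual crowding.
    Generates rotating Landolt-C stimulus trajectories with orientation jump
    points and sweeping target-flanker distances, simulates tracking observers
    with motor latency, pursuit lag, distance-dependent circular report noise
    and condition-specific post-jump recovery, and implements the full analysis
    chain: wrapped report errors, artifact cleaning, cosine-similarity tracking
    performance, regression-intersection and hinged-line crowding extents,
    Von Mises perceptual error, exponential-decay recovery rates, sequential
    t-test recovery times, and group-level repeated-measures inference.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
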