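Package: freerun
Title: Free-Running Circadian Period Analysis of Insect Locomotor Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of circadian locomotor activity recordings:
    reading beam-break monitor files and timed arena image stacks, scoring
    activity events from tracked positions by a displacement rule, estimating
    free-running periods in constant darkness with the normalized Lomb-Scargle
    periodogram, classifying animals as strongly rhythmic, complex, or
    arrhythmic, building double-plotted actograms, and comparing treatment
    groups with Dunnett's many-to-one post hoc test. Includes a seeded
    synthetic-data generator (activity records, Petri-dish trajectories,
    rendered frame stacks) with known ground truth so every stage of the
    pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    mvtnorm,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
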