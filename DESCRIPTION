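Package: rhythmscan
Title: Rhythmicity Detection and Comparison for Circadian Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects 24-hour rhythmic and pulsatile expression in probe-level
    time-course matrices (13 timepoints at 4-hour spacing over 48 hours, two
    replicates, light:dark or constant-dark regimes). Implements four
    detectors: a cosine goodness-of-fit test with an empirical
    permutation-based significance value (pMMCbeta), a nonparametric
    rank-correlation period/phase test with Benjamini-Hochberg q-values, a
    discrete-Fourier-transform relative-amplitude statistic for the 24-hour
    component, and a template-convolution score for pulsatile (spike)
    patterns. Provides consensus calling across detectors, phase and
    amplitude summaries, light-regime transition typing, hierarchical
    clustering, promoter consensus-element scanning, two-species
    rhythmic-ortholog comparison, and a fully seeded synthetic-data
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Biostrings,
    BiocGenerics,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
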