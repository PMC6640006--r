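Package: qcsfsim
Title: Simulated Quick CSF Testing and Binocular Summation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying binocular combination of contrast sensitivity
    with the quick CSF procedure. Implements the truncated log-parabola
    contrast sensitivity function and its scalar summaries (AULCSF, CSF
    acuity), a Bayesian adaptive engine that selects letter stimuli by
    expected information gain and estimates CSF parameters from
    ten-alternative forced-choice trials, a synthetic-observer generator
    emulating an amblyopia / strabismus / control cohort with configurable
    binocular combination regimes, a guessing-corrected probability-summation
    analysis of binocular performance, and a Monte-Carlo false-positive-risk
    calculation for group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
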