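Package: prtsway
Title: Dynamic Posturography with Pseudorandom Ternary Platform Tilts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-domain analysis of body sway during
    pseudorandom support-surface tilts. Designs pseudorandom ternary
    sequence (PRTS) tilt stimuli from a maximal-length shift register over
    GF(3), converts irregularly sampled 3D body-marker recordings into
    uniform-rate sagittal segment angles (head, shoulder, hip), estimates
    stimulus-to-segment transfer functions (gain, phase, coherence) at the
    excited harmonics by cross-spectral averaging over stimulus periods,
    and aggregates estimates across subject groups with confidence
    intervals, gain-ratio contrasts and repeated-measures ANOVA. Includes
    a synthetic multi-segment sway simulator with known ground truth
    (frequency-domain profiles and a delayed-feedback inverted-pendulum
    model) for end-to-end validation of the pipeline.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
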