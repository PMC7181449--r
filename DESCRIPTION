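Package: graspillusion
Title: Illusion Effects on Grip Aperture: Simulation, Kinematics and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether visual size illusions affect the maximum
    grip aperture (MGA) of reach-to-grasp movements. Provides a synthetic-data
    generator for matched-size judgements and 200 Hz thumb/finger marker
    trajectories under size-based, position-based or optimal-switch control of
    the grip; kinematic event detection (movement onset, near-target moment) and
    MGA extraction; the slope-scaled median illusion-effect statistic with
    percentage normalisation and size-category averaging; a Weber-law precision
    model generating the competing predictions for small and large objects; and
    the inferential layer (within-subject repeated-measures ANOVA computed from
    sums of squares, squared Pearson correlations, through-origin Weber-fraction
    fits, and noncentral-t power for one-sample designs). The end-to-end
    analysis is exposed as a single fitting function returning a classed object
    with print, summary, coef and plot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    signal
Config/testthat/edition: 3
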