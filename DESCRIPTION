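Package: mobilitykit
Title: Multi-Sensor Mobility Analysis for GPS and Accelerometer Wearables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipelines for analysing real-life mobility of older adults from
    wearable sensors. Cleans GPS trajectories and segments them into stop and
    move (trip) events with configurable dwell, radius and gap thresholds;
    derives daily life-space metrics (farthest distance from home, minimum
    convex hull, standard deviational ellipse) and travel mode from trip speed
    percentiles. Converts raw tri-axial accelerometry into per-minute activity
    counts, vector magnitude, Choi non-wear time, sedentary cut-point intensity
    classes, thigh-inclination postures and step counts. Provides the
    device-agreement statistics used in validation studies (Bland-Altman bias
    and limits of agreement, percent agreement, Spearman correlation, paired
    tests), plus a synthetic multi-device data generator with known ground
    truth and an end-to-end study orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
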