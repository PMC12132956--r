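Package: bezlid
Title: Upper Eyelid Contour Morphometry from Bezier Curve Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the upper eyelid margin from digitized cubic Bezier
    landmarks on external eye photographs. Calibrates pixels to millimetres
    with the white-to-white corneal diameter, normalizes each eye into a
    pupil-centred anatomical frame, and computes eye width, margin reflex
    distance (MRD1), contour peak location and height, palpebral fissure
    obliquity, the 13-angle radial mid-pupil lid distance (MPLD) profile and
    temporal-to-nasal MPLD ratios. Includes inter-rater reliability
    statistics (two-way random-effects intraclass correlation with absolute
    agreement, Bland-Altman limits of agreement, Welch t comparisons), a
    synthetic landmark generator with analytic ground truth for validation,
    file readers and writers for landmark and metric tables, and a command
    line interface.
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
    jsonlite,
    optparse
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
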