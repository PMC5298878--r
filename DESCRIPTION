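Package: cardiotrax
Title: Quantification of Cardiomyocyte Trajectories During Cardiac Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying directed collective cell migration from
    timelapse cell-track tables, built around the analysis of cardiomyocyte
    movement toward the embryonic midline during zebrafish cardiac fusion.
    Provides landmark-based drift correction against a reference track,
    left/right alignment into a common medial coordinate frame, per-cell
    kinematic metrics (speed, efficiency index, axis velocities, net
    direction), per-embryo aggregation, 10-bin angular (rose) histograms,
    pooled two-sample comparisons, and a bilateral-domain gap statistic
    (maximum of three anterior-posterior sample points 200 um apart).
    Includes a calibrated biased-random-walk trajectory simulator emulating
    wild-type and mutant cohorts for validation and power exploration.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
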