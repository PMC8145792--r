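Package: cervik
Title: Cervical Intervertebral Joint Kinematics from Sagittal Landmark
    Trajectories
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of cervical intervertebral joint motion recorded as
    2D sagittal osseous landmark trajectories (e.g. from videofluoroscopy).
    Converts named vertebral landmarks into midplane orientations and signed
    per-joint rotation trajectories referenced to the upright position,
    segments excursions into 10% time epochs, decomposes motion into pro- and
    anti-directional components, quantifies surplus motion (motion beyond
    end-range or beyond upright), classifies joints into Classic, Surplus and
    Anti-directional motion types, and aggregates cohorts into per-level,
    per-region and quartile summary tables with nonparametric group
    comparisons. Includes a synthetic trajectory and landmark generator
    carrying ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    nortest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
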