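Package: ligastiff
Title: In Vivo Knee Ligament Stiffness from Calibrated Balancer Video Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs tibiofemoral force-displacement curves of the medial
    and lateral knee ligament complexes from per-frame pixel coordinates of the
    scales of a calibrated spring-loaded knee balancer, estimates structural
    stiffness (N/mm) as the slope of the linear region of each curve, and
    summarizes patient cohorts. Includes the device calibration model, a
    perspective-robust per-frame scale digitization (length-ratio) geometry, a
    seeded synthetic forward model of the whole measurement chain (ground-truth
    ligament curve, balancer scale positions, camera pose and pixel noise) for
    parameter-recovery validation, and command-style entry points for
    simulation, fitting, and cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
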