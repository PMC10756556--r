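Package: gaitrec
Title: Ground Reaction Force Gait Analysis for Monitoring Functional
    Limb Recovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring functional limb recovery from single-axis
    force-platform recordings, as used in longitudinal follow-up of large-animal
    bone-regeneration studies. Provides stance-phase segmentation of vertical
    ground-reaction-force (GRF) traces with inclusion filters, extraction of
    body-weight-normalized gait parameters (peak and mean GRF, contact time, and
    two impulse variants), the classical inter-limb symmetry index, ordinary
    least-squares trend fitting with a limb-by-parameter R-squared matrix, and
    estimators of recovery time and recovery rate. A seeded synthetic gait
    generator emulates healthy M-shaped and post-operative single-hump stance
    curves, compensatory loading of the non-operated limbs, and linear recovery
    trajectories, so the full pipeline can be exercised and validated without
    any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
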