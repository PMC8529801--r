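Package: flow4d
Title: Right-Heart Hemodynamics from 4D Flow Cardiovascular MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of time-resolved three-directional
    phase-contrast (4D flow) cardiovascular MRI velocity fields, aimed at
    right-heart hemodynamics. Provides retrospective ECG gating assessment
    and repair, respiratory gating at a target efficiency, cardiac phase
    binning, stationary-tissue background phase correction by third-order
    polynomial fitting, through-plane flow quantification in a vessel
    (flow curves, stroke volume, cardiac output, body-surface-area
    indexing), ventricular kinetic energy, energy efficiency and vorticity
    with systolic/diastolic peak extraction, streamline and pathline
    tracing, and age-adjusted group comparisons by linear regression with
    a dummy-coded group variable. Includes analytic 4D velocity phantoms
    (pulsatile tubes, vortices, trigger and respiration simulators) with
    closed-form ground truth so every stage can be validated without
    scanner data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
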