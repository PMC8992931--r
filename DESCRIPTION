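Package: stereomu
Title: Independent Monitor-Unit Verification for Stereotactic Cone Plans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Secondary monitor-unit (MU) check for stereotactic radiosurgery
    plans delivered with circular conical collimators. From commissioning
    beam data (tissue-maximum-ratio curves per cone, output factors,
    absolute calibration, a Hounsfield-unit to relative-electron-density
    curve) and a DICOM-RT study (CT series, RT Plan, RT Structure Set,
    RT Dose) it recomputes the MU of every static field or arc at the
    isocenter using the TMR formalism, with and without an
    equivalent-path-length heterogeneity correction obtained by exact
    (Siddon-type) ray tracing through the CT volume, and reports percentage
    differences against the planning system for QA action-level screening.
    Includes a synthetic-fixture generator that writes analytic beam-data
    archives and DICOM-like phantom studies with known-answer MU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
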