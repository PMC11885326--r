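Package: neoaorta
Title: Synthetic Hemodynamic Analysis of the Neo-Aorta After Arterial Switch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale hemodynamic analysis pipeline for post-arterial-switch
    neo-aortas. Generates synthetic phenotype-specific aortic geometries and
    time-periodic pulsatile velocity fields, tunes three-element Windkessel
    (RCR) outlet models to systolic/diastolic pressure targets in a 0-D
    lumped-parameter network, and computes the standard post-processing
    metrics of aortic CFD studies: regional time-averaged wall shear stress,
    slice-averaged vorticity, aortic arch angle, recirculation-zone
    detection, Haycock body surface area, aortic-root Z-scores and dilation
    classes, ending in group-level comparison of severe / mild / normal
    dilation cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
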