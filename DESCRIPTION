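Package: cdar
Title: Computed Digital Absorptiometry for Radiographic Bone Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relative bone mineral density quantification from plain
    radiographs by computed digital absorptiometry (CDA). An aluminum
    step-wedge density standard imaged beside the joint provides per-step
    reference attenuation ranges (Hounsfield-like units) that are used to
    decompose a radiograph into color-annotated images, count color pixels by
    CIE76 similarity against a white (bone) reference, detect and grade
    background artifacts, and compare X-ray tube settings statistically
    (repeated-measures ANOVA with Holm-Sidak post hoc, Friedman with Dunn
    post hoc). A synthetic radiograph generator (Beer-Lambert projection of a
    stepped wedge and a knee-like phantom with controllable tube voltage,
    tube current-time product, noise, and hair-like background clutter) makes
    the full pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
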