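Package: octbands
Title: Quantification of Outer Retinal Bands in Geographic Atrophy from
    OCT Layer Segmentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify outer retinal bands (ELM+MZ, EZ, RPE) in
    geographic atrophy from optical coherence tomography (OCT)
    layer-segmentation surfaces.  Computes en-face thickness maps,
    band-loss masks and areas, subretinal drusenoid deposit (SDD)
    thickness maps and volumes, fovea-centered ETDRS-grid topographic
    summaries, and two-device or between-region comparisons with linear
    mixed-effects models that account for inclusion of both eyes of a
    patient.  Includes a synthetic phantom-eye generator with analytic
    ground truth (elliptical atrophy lesions, drusen elevations,
    paraboloid SDD mounds, paired two-device acquisitions) for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
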