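Package: redoximg
Title: Optical Redox Imaging Quantification of Macrophage Mitochondrial
    Redox State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies label-free optical redox imaging (ORI) of NADH and
    flavoprotein (Fp) autofluorescence in cultured and ex vivo lung
    macrophages. Implements background subtraction, signal-to-noise-ratio
    thresholding, pixel-wise redox-ratio (Fp/(NADH+Fp)) image generation,
    and field-of-view and sample-level aggregation, together with
    experiment-level analyses: oxidant dose-response fits, FCCP/rotenone +
    antimycin A redox-titration dynamic ranges, ratiometric lipid
    peroxidation indices, many-to-one group comparisons with a Monte-Carlo
    Dunnett adjustment, and clinical-covariate regressions for tracheal
    aspirate cohorts (gestational age, postmenstrual age, FiO2, mean airway
    pressure, respiratory severity score). A synthetic-scene generator with
    known ground truth supports end-to-end validation without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
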