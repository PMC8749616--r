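Package: thermotex
Title: Texture Analysis of False-Color Thermal Images for Pregnancy
    Detection in Mares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for infrared-thermography image texture analysis
    aimed at non-contact pregnancy detection in mares. Decomposes 8-bit
    false-color thermograms into ten color components (RGB, YUV, YIQ, HSB),
    extracts 13 first-order histogram statistics and 11 Haralick features
    from symmetric (GLCM) and asymmetric (GLCH) gray-level co-occurrence
    matrices inside a flank region of interest, screens the 350
    color/feature combinations through a three-criterion statistical
    cascade (non-pregnant homogeneity, sustained pregnant/non-pregnant
    separation, monotone gestational trend), and evaluates threshold-based
    diagnostic accuracy (sensitivity, specificity, predictive values).
    Includes a seeded synthetic thermal-cohort generator emulating the
    longitudinal study design the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    yaml,
    jsonlite,
    withr,
    pracma,
    rlang
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
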