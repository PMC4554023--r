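Package: astigvec
Title: Power-Vector Analysis of Corneal Astigmatism and Ocular Residual
    Astigmatism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Double-angle (Jackson) power-vector analysis of corneal and
    refractive astigmatism: conversion between cylinder/axis and (J0, J45)
    representations, difference metrics between keratometry modalities,
    vertex-distance transport of manifest refraction to the corneal plane,
    surgically induced astigmatism adjustment, and ocular residual
    astigmatism (ORA). Includes a synthetic per-eye cataract cohort
    generator, cohort-level analysis (with-the-rule/against-the-rule and
    corneal-irregularity subgroups, log-linear regressions, group
    comparisons) and a flat-CSV cohort interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
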