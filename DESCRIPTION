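Package: cardioquant
Title: Quantification of Cardiomyocyte Electrophysiology, Calcium Handling
    and T-Tubule Organization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction for cardiotoxicity phenotyping of isolated
    cardiomyocytes. Computes action-potential features (APD50/APD90, diastolic
    potential, upstroke velocity), beat-to-beat repolarization variability
    (short-term variability and Poincare pairs), delayed and early
    afterdepolarization detection, Ca2+ transient kinetics with caffeine-based
    SR content estimation, Ca2+ spark detection and parameterization on
    confocal line-scan images with derived spark-mass/leak/ember indices, and
    a spatial-FFT T-tubule regularity index. Includes synthetic-data
    generators with closed-form ground truth for every analysis stage, and a
    group-comparison layer (t/ANOVA with Bonferroni correction, chi-square for
    categorical flags).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    minpack.lm,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
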