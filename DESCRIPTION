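Package: grsforest
Title: Weighted Genetic Risk Scores for Post-Bariatric Weight Loss with
    Random-Forest Variant Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of weighted genetic risk scores
    (GRS) for excess-BMI-loss after Roux-en Y gastric bypass surgery.
    Implements effect-allele dosage coding from VCF or tabular genotypes,
    Hardy-Weinberg, minor-allele-frequency and linkage-disequilibrium
    quality control, beta-weighted SNP scoring, random-forest permutation
    importance filtering with a relative percent-MSE cutoff, a
    direction-aware allele-coding inversion step, and covariate-adjusted
    linear association models with Benjamini-Hochberg-corrected quartile
    contrasts.  A synthetic-cohort generator with planted additive SNP
    effects makes the full pipeline testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
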