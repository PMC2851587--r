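Package: lfqpep
Title: Label-Free LC-MS Peptidomics: Normalization, Multivariate Class
    Models and Factorial Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for label-free liquid-chromatography
    mass-spectrometry peptidomics of a randomized-block study design.
    Provides a peptide toolkit (monoisotopic MH+ with post-translational
    modifications, prohormone cleavage-site prediction), two-step run
    normalization (linear calibration to a median reference run followed
    by per-peptide lowess run-order drift correction), group-missingness
    filtering and technical-replicate collapsing, PCA and PLS-DA with
    cross-validated Q2, VIP scores with jackknife confidence intervals
    and Hotelling T2/DModX diagnostics, per-peptide three-way factorial
    ANOVA with marginal (Type III) sums of squares and
    Benjamini-Hochberg FDR, and a seeded synthetic-data generator with
    intensity-dependent (MNAR) missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    car,
    emmeans,
    withr
Config/testthat/edition: 3
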