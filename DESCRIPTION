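Package: ironmr
Title: Two-Sample Mendelian Randomization of Systemic Iron Status on
    Kidney Disease Risk
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-sample Mendelian randomization (MR) of systemic
    iron status, measured by four correlated biomarkers (serum iron,
    ferritin, transferrin saturation and total iron-binding capacity), on
    binary disease outcomes such as IgA nephropathy, acute kidney disease
    and chronic kidney disease.  Covers GWAS summary-statistic input and
    effect-allele harmonization, instrument selection under three nested
    strategies with LD clumping, proxy lookup, MHC and confounder
    exclusion, instrument-strength F statistics and design-based power;
    univariable estimators (fixed- and multiplicative random-effect
    inverse-variance weighting, simple, weighted and penalized weighted
    medians, MR-Egger) with Cochran's Q and Egger-intercept sensitivity
    analyses; a mixture-model estimator robust to invalid instruments; and
    multivariable MR by Bayesian model averaging with per-instrument
    outlier diagnostics.  A seeded generator of synthetic GWAS summary
    statistics with the assumed latent-factor structure makes every stage
    runnable and testable without access to the source cohorts.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
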