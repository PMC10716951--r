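Package: mrpath
Title: Two-Sample Mendelian Randomization with Two-Step Mediation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimators and tooling for two-sample Mendelian randomization (MR)
    from GWAS summary statistics: allele harmonization, linkage-disequilibrium
    clumping and instrument selection, inverse-variance weighted (IVW), MR-Egger,
    weighted median and mode-based estimators with heterogeneity and instrument
    strength diagnostics, the MR-PRESSO global and outlier tests with
    outlier-corrected estimates, multivariable MR (MV-IVW and MVMR-Egger), and
    two-step MR mediation via the product-of-coefficients method with
    delta-method standard errors, mediation proportions, false discovery rate
    control and evidence grading. Includes a seeded generator of multi-trait
    GWAS summary statistics under explicit causal diagrams for validation by
    parameter recovery, and a two-phase pipeline (total effects, then mediator
    screening and quantification).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
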