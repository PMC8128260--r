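Package: mrdliquid
Title: Minimal Residual Disease Analysis from Serial ctDNA Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tumor-informed circulating tumor DNA (ctDNA) analysis of
    minimal residual disease after curative-intent surgery. Implements
    UID-family (molecular barcode) consensus calling of supermutants and
    mutant allele fraction (MAF), permutation-based ctDNA positivity testing
    against a control panel, mixed-effects modelling of longitudinal log-MAF
    dynamics during chemotherapy with cluster-robust standard errors,
    Kaplan-Meier estimation with Greenwood variances, the Klein fixed-time
    two-sample survival test, Cox proportional-hazards regression with the
    exact partial likelihood for tied event times, cohort-level association
    and power statistics, and a synthetic cohort generator that emulates the
    statistical structure of a resected colorectal-liver-metastasis MRD
    study so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr
Config/testthat/edition: 3
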