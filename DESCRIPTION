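Package: methdelta
Title: Longitudinal EWAS of Infant Feeding on Delta-Residual DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association analysis of infant feeding
    modes (exclusive breastfeeding, exclusive formula feeding, mixed feeding)
    on the change in blood DNA methylation between birth and late childhood.
    Implements beta/M-value transformation and probe quality control,
    per-timepoint residualization of M-values on leukocyte cell-type
    proportions and season of blood collection, construction of
    delta-residuals (age-10 minus birth), training/testing screening of
    candidate CpGs with robust (Huber) regressions and surrogate variables,
    confounder-adjusted per-CpG regression with Benjamini-Hochberg false
    discovery control, epigenome-wide methylation-shift statistics
    (per-subject mean delta and quartile-percentage outcomes), cohort
    representativeness tests, a mixed-model temporal-stability classifier,
    and a synthetic-cohort generator with known ground truth for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    lme4,
    lmerTest,
    ggplot2,
    rlang,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
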