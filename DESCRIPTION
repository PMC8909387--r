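Package: cnatme
Title: Copy-Number Instability Scores and Tumor-Microenvironment Survival Analysis
Version: 0.1.0
Authors@R:
    person("cnatme", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scores genomic instability in shallow copy-number profiles of
    high-grade serous ovarian carcinoma and relates it to the tumor immune
    microenvironment and survival. Implements the Genomic Index (GI = A^2/C),
    focal/arm/chromosome somatic copy-number alteration scores, and a
    shallowHRD-style large-genomic-alteration (LGA) counter with homologous
    recombination deficiency (HRD) calling; probe-level log-ratio
    segmentation by recursive binary splitting with permutation-tested
    change points; immunohistochemistry marker scoring (H-score,
    best-cutoff binarization, cross-tabulations); and a survival layer
    (Kaplan-Meier, log-rank, Cox, maximally selected rank statistic
    cutpoints, bootstrap lasso-Cox stability selection). A synthetic cohort
    generator with controlled LGA counts, HRD-correlated markers and
    proportional-hazards survival makes the whole pipeline testable without
    patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    optparse,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
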