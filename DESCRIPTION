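Package: cawi
Title: Complexity-Adjusted Waste Index for Hospital Hazardous-Waste Benchmarking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Complexity-Adjusted Waste Index (CAWI) and the
    companion indicators used to benchmark hazardous healthcare waste (HHCW)
    generation across inpatient institutions: the raw generation rate
    (kg/bed/day), the Case-Mix Index (CMI) from DRG case tables, and the
    average Length of Stay (LOS). Provides quintile-based size stratification
    with group summaries, a comparative statistical battery (Shapiro-Wilk
    normality screening, two-sided variance F-test, Spearman rank correlation,
    Fisher z and Steiger tests for comparing correlation coefficients, and
    Huber M-estimation robust regression with residual diagnostics), a
    synthetic hospital-panel generator with known ground truth for validation
    studies, and an end-to-end pipeline that reads institution-year panels
    from CSV and writes reproducible JSON/CSV validation reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
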