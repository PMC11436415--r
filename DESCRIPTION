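Package: mtdrive
Title: Composite Scoring and Biomarker Association Analysis for Remote
    Self-Administered Cognitive Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scoring of the Mayo Test Drive (MTD) remote cognitive
    screening battery and analysis of its associations with imaging
    biomarkers of Alzheimer's disease. Implements the Stricker Learning
    Span and Symbols Test derived variables, the accuracy-weighted
    response-time metric (SYMaw), the raw and z-score screening battery
    composites (MTD-SBCr, MTD-SBCz), reference-group (cognitively
    unimpaired) z-standardization, imaging-biomarker preparation
    (log/z-transformed SUVRs, sex-specific intracranial-volume adjustment
    of hippocampal volume, percent white-matter-hyperintensity volume),
    covariate-adjusted standardized linear-model associations, Hedge's g
    effect sizes with confidence intervals from raw data or published
    summaries, Spearman correlations by diagnostic group, and a calibrated
    synthetic-cohort generator for end-to-end testing without access to
    restricted cohort data.
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
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
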