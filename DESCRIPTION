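Package: nbstiming
Title: Age at Blood Collection Effects in Newborn Metabolic Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how the age at blood collection (AaBC) shifts
    tandem mass-spectrometry metabolite levels in newborn screening and how
    those shifts alter false-positive rates for inborn metabolic disorders.
    Provides a synthetic-cohort generator with configurable analyte
    trajectories, covariate effects and lognormal noise; cohort exclusion and
    reference-restriction rules with both fine (6-hour) and coarse
    (early/standard/late) collection-window binning; Cohen's d effect-size
    matrices with marker flagging and two-cluster trajectory clustering;
    penalized-spline (GAM) smoothing of analyte-versus-age curves with
    pointwise confidence bands; and observed-versus-expected false-positive
    enrichment tests with consistency classification against marker-level
    effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    mgcv,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
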