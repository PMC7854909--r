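---
title: "Methods: collection-timing effects on screening analytes and false positives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collection-timing effects on screening analytes and false positives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbstiming)
```

## The problem

Dried-blood-spot screening for inborn metabolic disorders measures a panel
of 41 amino acids and acylcarnitines by tandem mass spectrometry, usually
24–48 h after birth. During the first days of life a newborn transitions
from placental supply to autonomous metabolism, so analyte levels move
quickly: some fall (for example phenylalanine and free carnitine), some
rise (long-chain acylcarnitines such as C18:1), and some dip before rising
(leucine–isoleucine). A screen drawn early (12–23 h) or late (49–168 h)
therefore samples a different physiological state than the standard window,
and with fixed cutoffs that shifts the false-positive rate of any disorder
whose primary marker is age-sensitive.

`nbstiming` implements the full analysis chain for this question:

1. cohort exclusion and reference restriction rules;
2. effect-size profiling of every analyte across collection-age bins;
3. two-cluster profiling of analyte trajectories;
4. penalized-spline smoothing of analyte-versus-age curves per covariate
   stratum;
5. observed-versus-expected false-positive enrichment per collection
   window, with a consistency classification linking marker shifts to
   false-positive shifts;
6. a synthetic-cohort generator so that all of the above is testable
   without access to restricted registry data.

## Cohort rules and binning

Records are excluded when age at blood collection (AaBC) is unknown or
outside 12–168 h, birth weight outside 1,000–5,000 g, gestational age
outside 28–42 weeks, or (when enabled) TPN status is positive or unknown.
Exclusion tallies use first-matching-rule attribution in the fixed order
aabc → bw → ga → tpn so that counts are reproducible. Analyses of analyte
levels then restrict to a reference subset — term infants (37–41 weeks),
birth weight 2,500–4,000 g, no TPN — to control the three covariates with
the largest influence on marker levels. All interval endpoints are
inclusive on integer hours, grams and weeks; fractional hours are floored
on ingest. Records carrying several reported race/ethnicity categories are
reclassified by the program cascade Hispanic > Black > Asian > White-only,
everything else Other/Unknown.

Two binning systems are used. Fine profiling uses ten 6-h windows over
12–72 h (12–17, 18–23, …, 66–72; the last window is 7 h wide; hours after
72 are too sparse to profile), with the 12–17 h window as reference so the
gradual postnatal change is visible. Window comparisons use three coarse
categories — early 12–23 h, standard 24–48 h, late 49–168 h — with the
standard window as reference. Fine bins are indexed 0–9 (0 = reference) to
keep the window arithmetic explicit.

## Effect sizes

Group differences are quantified by Cohen's d: the difference of two group
means divided by the pooled standard deviation
\\(s_p^2 = ((n_x-1)s_x^2 + (n_y-1)s_y^2)/(n_x+n_y-2)\\), positive when the
comparison window is above the reference. Because d is not driven by
sample size it allows a 90,060-record window to be compared with a
305,674-record one on equal terms; the suite verifies location/scale
invariance and (asymptotic) invariance under record replication. No
small-sample bias correction (Hedges' g) is applied, matching common
screening-program practice. An analyte/window cell is *flagged* when
|d| > 0.2 (strict), and called strong at |d| ≥ 0.5.

Trajectory profiles (the 9-vector of fine-bin d values per analyte) are
grouped by agglomerative hierarchical clustering with Euclidean distance
and complete linkage — a conventional choice for small trajectory sets;
both are parameters. The two-cluster cut is labeled by the sign of the
mean terminal-bin d ("decreasing" vs "increasing"). Missing cells are
imputed by within-row linear interpolation for clustering only, never for
reported effect sizes.

## Smoothed trajectories

Conditional-mean curves of analyte level versus AaBC per stratum use a
penalized cubic regression spline (15 basis functions, penalty chosen by
generalized cross-validation) fitted with `mgcv`, evaluated on the integer
hour grid 12–168 restricted to the observed AaBC range, with pointwise
normal-approximation 95% bands for the mean. Fits refuse strata under 200
records — sparse late-collection strata otherwise produce unstable
curves — and degenerate AaBC spreads. Windowed stratum comparisons report
the averaged fitted-mean difference over the window, with the p-value from
a Welch two-sample test on the raw records inside the window: testing raw
data rather than smoothed curves avoids inheriting the smoother's bias,
though it is an implementation choice rather than an established
convention for this analysis.

Simulation places the empirical pointwise coverage of the 95% band around
92–95% (the shortfall from nominal is smoothing bias near the boundaries),
which is why the package's own guarantee is stated as ≥ 90% coverage;
per-cohort covered fractions vary widely because neighbouring grid points
are strongly correlated, so coverage checks average over many simulated
cohorts.

## False-positive enrichment

For each disorder the false-positive cases (restricted to the same
GA/BW/TPN reference ranges as the screen-negatives) are tallied per
collection window. Under no timing effect the counts should split in
proportion to the screen-negative window sizes (90,060 / 305,674 / 19,135),
giving expected counts \\(E_i = N \\cdot n_i / \\sum n\\). Two tests are
computed: an overall Pearson chi-squared of the three observed counts
against expectation (df = 2), and a per-window one-sample two-cell
chi-squared of (obs, total − obs) against the fixed screen-negative share
(df = 1, no continuity correction — the screen-negative cohort is three
orders of magnitude larger than any false-positive series, so treating its
share as fixed is numerically indistinguishable from a 2×2 test).
Significance is tiered at 0.05 / 0.01 / 0.001 and no multiple-testing
correction is applied by default. Display rounding of expected counts is
nearest integer with ties away from zero, which reproduces the published
reference table cell for cell (one cell of that table is inconsistent with
any single rounding rule; the packaged fixtures keep the printed value and
the tests document the difference).

A marker flagged in a window predicts the direction of the
false-positive shift there: an *elevated*-marker disorder should gain
false positives where healthy levels are raised, and a *decreased*-marker
disorder should lose them (and vice versa). The consistency call is
`consistent` when the observed−expected sign matches this prediction and
the enrichment is significant, `inconsistent` when significant with the
opposite sign, and `indeterminate` when the marker is unflagged
(|d| ≤ 0.2) or the enrichment is not significant. The significance gate
defaults to the overall df = 2 test: the per-window test is insensitive to
small late-window counts (for IVA, 1 observed vs 1.3 expected late cases
yields p ≈ 0.76 while the whole table departs from expectation at
p ≈ 0.037), and the overall gate reproduces the published qualitative
calls for all nine disorders. `p_source = "category"` switches to the
per-window gate.

## The synthetic-cohort generator

Restricted registry data cannot ship with the package, so the generator
produces cohorts with the statistical structure the analysis assumes, and
every guarantee is demonstrated on them:

* **Trajectories.** Each analyte's mean is one of four parametric
  templates on 12–168 h: exponential decay to a plateau, saturating rise,
  fast-decay-plus-slow-rise (dip then rise), or constant. The default
  41-analyte panel (11 amino acids, 30 acylcarnitines, abstract
  concentration units with µmol/L semantics) assigns 20 decreasing and 21
  increasing templates with relative amplitude 0.35 and rate 0.04/h
  (half-change ≈ 17 h), matching the qualitative two-cluster structure of
  population screening data.
* **Noise.** Multiplicative lognormal with unit mean and CV 0.25 —
  concentrations stay positive and right-skewed.
* **Covariates.** Gestational age (≈ 7.7% preterm), birth weight rising
  130 g/week around 3,400 g at 39 weeks, a 51.5/48.5 sex split, a
  race/ethnicity report mix dominated by Hispanic (50%) and White (26%)
  reports with 15% multi-category reports, and rare TPN (0.6%). Covariate
  effects enter the mean multiplicatively as `exp(offset × σ_log)` —
  additive offsets in log-SD units — which reproduces stratified
  separations such as raised preterm and TPN levels.
* **Collection ages.** Hour weights with category masses 21.7% / 73.7% /
  4.6% (early/standard/late), peaked around 24–40 h with a geometric late
  tail.
* **Planted effects.** `plant_effect()` shifts one analyte's mean by a
  chosen number of noise-SD units uniformly over one window, as an
  additive location shift applied after noise: group variance is
  untouched, repeated plants add exactly, and the downstream Cohen's d of
  the planted window against an unshifted one recovers the planted value —
  the parameter-recovery contract the acceptance checks exercise at
  ~50,000 records per group (tolerance ±0.05, about eight standard errors).
  `null_config()` provides flat-trajectory cohorts for null calibration:
  only there is "no planted effect implies d ≈ 0" meaningful, since a
  sloped trajectory makes windows differ by construction.
* **False positives.** Per disorder, a total count and window shares;
  cases draw a window multinomially and an hour uniformly within it, with
  reference-compliant covariates.

One global seed expands into fixed per-stream sub-seeds (cohort, case
table), so identical configurations reproduce byte-identical TSV
artifacts.

What the generator does **not** emulate: correlations between analytes,
analyte ratios, true-positive disease biochemistry, seasonal or laboratory
batch effects, or any fit to real registry marginals. Passing tests
therefore demonstrate that the *machinery* is correct and calibrated —
not that real cohorts follow these particular trajectory shapes.
Registry-dependent headline numbers (specific d values, the fraction of
flagged metabolites) are only reproducible from the published count
tables shipped in `inst/extdata/`, which is exactly how the package's
checks treat them.

## Problem sizes and numerics

The shipped tests run the generator at 30,000–100,000 records (about
50,000 per compared window for recovery checks, where the sampling error
of d is ≈ 0.006), 2,000 replicate tables for chi-squared calibration, and
100–200 simulated cohorts of 2,000–10,000 records for band coverage —
sizes at which every guarantee is comfortably resolved on a laptop core in
about a minute. Degenerate inputs are errors, not silent results: zero
pooled SD, groups under 2 records, strata under 200 records, expected
counts of zero, and category shares outside (0, 1) all raise descriptive
errors; expected counts below 5 warn. Concentrations are floored at the
smallest positive double (the lognormal noise model makes smaller values
astronomically unlikely at realistic CVs; the floor only guards extreme
planted negative shifts).

## Known limitations

* The consistency rule reconstructs a published qualitative definition
  from its verbal description; borderline cells (tiny case series such as
  HCY with 12 false positives) are deliberately `indeterminate`.
* GCV-selected smoothness slightly undercovers at the grid boundaries;
  use wider bands or REML if calibrated pointwise inference at 12 h or
  168 h matters.
* The exclusion tally attributes each record to a single rule
  (first-match), so tallies do not report overlaps between violated rules.
* Sex-"unknown" records are retained except in sex-stratified analyses.
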