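---
title: "Brain-age monotonicity and connection-count analysis: methods"
author: "connectomeAge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age monotonicity and connection-count analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectomeAge)
```

## The scientific question

Resting-state fMRI connectivity patterns change with age, but it is not
obvious whether they change *monotonically*: do brains of intermediate age
look, to a classifier, progressively more like old brains? This package
implements a classification-based probe of that question. A linear
support-vector machine is trained to distinguish a young from an aged
extreme group and is then shown connectivity patterns of subjects at ages
it has never seen. If aging is progressive, the percentage of subjects
classified as "aged" should rise steadily across the unseen interval.

Three interval designs ask complementary questions:

* **Interval 1** trains on the youngest and oldest groups and tests all
  intermediate ages — the direct monotonicity probe.
* **Interval 2** trains on the two *youngest* groups and tests all older
  subjects — do differences among young brains anticipate later aging?
* **Interval 3** trains on the two *oldest* groups and tests all younger
  subjects — do differences among aged brains reflect dynamics earlier in
  life?

A second, complementary analysis quantifies connectivity directly: for
each subject, the number of edges whose Pearson correlation exceeds a
magnitude threshold is counted, separately for positive correlations and
anticorrelations, and compared per age decade and per sex against the
youngest group.

## Data representation

A subject's connectivity pattern is the vector of Pearson correlations
between the time courses of all unordered ROI pairs: `featureDimension(R)`
= R(R−1)/2 values (861, 9730 and 326,028 for parcellations of 42, 140 and
808 regions). Edges are ordered row-major along the upper triangle —
(1,2), (1,3), …, (1,R), (2,3), … — a fixed convention (`edgePairs()`) so
that a feature index always maps to the same ROI pair. Cohorts are stored
as a `ConnectomeCohort`, a `SummarizedExperiment` with edges in rows,
subjects in columns, and age/sex/site/eyes metadata in `colData`.

## The monotonicity pipeline, step by step

Given group sizes $N_1$ (young) and $N_2$ (aged):

1. $m = \min(N_1, N_2)$; train on all $m$ subjects of the smaller group
   and a seeded uniform subsample of $m$ from the larger, so classes are
   exactly balanced (`balancedSplit()`).
2. Fit a linear-kernel SVM (hinge loss, L2 penalty, $C = 1$) on the $2m$
   connectivity patterns. Features are standardised per edge with the
   *training-set* mean and s.d.; the identical transform is applied to
   validation and test data. $C = 1$ with standardisation mirrors the
   default behaviour of the standard SVM toolchains for this analysis.
3. The $k = \max(N_1, N_2) - m$ left-out subjects of the larger group are
   validation data; the fraction classified correctly is the accuracy rate
   (AR). When $k = 0$ the AR is undefined and reported `NA`.
4. Classify every subject in the unseen test bins, tally the percentage
   classified as aged at each integer age (`percentAgedByAge()`), and
   optionally pool sparse terminal ages into one subject-weighted point
   (`poolTailAges()`, off by default; the reference analyses end the
   abscissa at a pooled point when every age beyond a cutoff has fewer
   than 3 subjects).
5. Smooth the series with a 5-year sliding window: the value at age $a$
   becomes the unweighted mean of the raw percentages at *observed* ages
   within $[a-2, a+2]$, truncating at the interval edges. Width 1 is the
   identity and reproduces the no-smoothing variant.
6. Fit ordinary least squares of percent on years-since-interval-start,
   giving intercept $\beta_0$ and slope $\beta_1$, and compute Spearman's
   rank correlation $\rho_s$ (average ranks for ties) between age and the
   smoothed percentages. Both statistics are also emitted for the raw
   series, since smoothing systematically inflates $|\rho_s|$ on short
   series (adjacent smoothed values share most of their window).
7. Map $(\beta_0, \beta_1, \rho_s)$ to a trajectory hypothesis.

### The hypothesis rule

The published assignment of H-labels is narrative; the package formalises
it as an explicit, configurable rule (`selectHypothesis()`):

* any interval: **H1** (monotone increase) iff $\rho_s \ge 0.5$ and
  $\beta_1 > 0$;
* interval 2 fallback: **H2** iff $\beta_1 > 0$ and $\beta_0 < 50$
  (rising from a young-like start), otherwise **H3** (flat, high
  intercept);
* interval 3 fallback: **H2** iff a quadratic fit to the series has
  significantly negative curvature at $p < 0.05$ (the inverted-U
  trajectory), otherwise **H3**;
* interval 1 fallback: `"inconclusive"` — no published case required it.

The thresholds ($\rho_s \ge 0.5$; $\beta_0 < 50$; curvature $p < 0.05$)
were calibrated once so that the rule reproduces all twelve published
(interval, $\beta_0$, $\beta_1$, Spearman) → hypothesis assignments, and
are exposed as arguments rather than constants. The regression x-origin
(years since the youngest test age) is likewise a design choice: a raw-age
origin would produce large negative intercepts, inconsistent with
published intercepts such as $\beta_0 = 0$, but it is not stated in the
source analyses and can be switched (`origin = "age_zero"`).

```{r hypothesis}
selectHypothesis(1, 31.58, 0.952, 0.7)
selectHypothesis(2, 82.159, 0.1, 0.149)
```

## Connection-count quantification

`countFC()` counts edges with $\rho > t$ (positive) and $\rho < -t$
(negative/anticorrelated); the total is their sum. "Exceeds" is read as a
*strict* inequality — boundary values are excluded, a measure-zero event
for empirical correlations. The customary threshold is $t = 0.6$, with
0.45 and 0.7 as sensitivity settings (`thresholdSensitivity()`); because
the inequality is strict, every count is monotone non-increasing in $t$.

`summarizeFC()` reports, per age bin and optionally per sex stratum, the
mean and sample s.d. ($n-1$ denominator) of the three count classes, and a
two-sided *Welch* (unequal-variance) t-test of each class against the
youngest bin present in the same stratum, significant at $p < 0.05$. The
Welch form was chosen because count variances differ visibly across age
groups; the source analyses say only "two-sample t-test". No
multiple-testing correction is applied by default, matching the fixed
$p < 0.05$ criterion, but `adjust = "BH"` enables Benjamini–Hochberg.
Strata with fewer than two subjects are summarised with the test skipped
and flagged. `filterCohort()` restricts a cohort by recording site,
arousal state (eyes open/closed) or sex with intersection semantics, for
single-site and eyes-open replications.

## The synthetic cohort generator

Real multi-site rsfMRI cohorts cannot be redistributed, so the package
ships a generator (`generateCohort()`) whose cohorts carry exactly the
statistical structure the analysis assumes — no more. Each edge's latent
Fisher-z value is

$$ z_e = b_{c(e)} + d(a)\, s(\mathrm{sex})\, \mathbf{1}[e \in A] +
   \varepsilon_e, \qquad \varepsilon_e \sim N(0, \sigma(a)^2), $$

and the observed correlation is $\tanh(z_e)$, which keeps features
strictly inside (−1, 1) and makes effect sizes additive on the z scale.

* $b$: baseline 0.35 for within-network and 0.10 for between-network
  edges (ROIs partitioned into 4 contiguous blocks) — typical magnitudes
  for within- vs between-system resting-state correlations.
* $d(a)$: age drift, one of linear, plateau-after-40, inverted-U, or
  null; default magnitude 0.01 z/year applied to a fixed random 30% of
  edges. Over the 18–85 span this is ≈ 0.67 z ≈ 4.5 noise s.d., a strong
  but not degenerate effect.
* $\sigma(a)$: inter-subject s.d., constant 0.15 z by default, with
  inverted-U (middle-age peak) and decreasing profiles available to
  emulate the reported variance trajectories.
* $s$: per-sex drift multiplier (1.5 for males under the
  `sex_accentuated` preset, emulating effects more pronounced in males).

The default group structure (`defaultGroupSpec()`) uses six decade bins
18–85 with 200 subjects in the youngest bin and 40 in each later bin,
mirroring the right-skewed age distributions of public cohorts and
leaving a large residual validation set ($k = 160$ for interval 1). Ages
are sampled uniformly as integer years within each bin, since the
analysis tallies by integer age. `scenarioPreset()` names five regimes
(monotone, plateau, null, inverted-U variance, sex-accentuated) with
these defaults fixed.

In time-course mode the sampled correlation pattern is projected to the
nearest positive-semidefinite correlation matrix (eigenvalue clipping at
zero, then rescaling to unit diagonal — `nearestPSDCorr()`) and a
$T \times R$ Gaussian series is drawn from it, so that the Pearson
feature-extraction path is exercised end-to-end.

**What the generator does not emulate:** BOLD haemodynamics, temporal
autocorrelation, motion artefacts, scanner/site noise, spatial structure
beyond the block partition, and non-Gaussian inter-subject heterogeneity.
Passing tests on synthetic cohorts therefore demonstrate that the
*pipeline* recovers the regimes it is designed to detect; they say
nothing about effect sizes in real recordings, for which no public
redistribution was possible here.

## A worked run

```{r run}
cc <- generateCohort(scenarioPreset("monotone", seed = 11))
binning <- AgeBinning(c("18-30", "31-40", "41-50", "51-60", "61-70",
                        "71-85"),
                      c(18, 31, 41, 51, 61, 71),
                      c(30, 40, 50, 60, 70, 85))
res <- runMonotonicity(cc, 1, binning, seed = 5)
res
```

A null cohort, by contrast, yields chance-level validation accuracy and a
raw-series $\rho_s$ near zero:

```{r nullrun}
nullCohort <- generateCohort(scenarioPreset("null", seed = 3))
resNull <- runMonotonicity(nullCohort, 1, binning, seed = 5)
c(AR = resNull@validationAccuracy, rawRho = resNull@rawSpearmanRho)
```

Note the smoothed-series $\rho_s$ is *not* a good null diagnostic: with
roughly 40 distinct test ages, a 5-year moving average leaves about 8
effectively independent points, inflating the null spread of the rank
correlation by a factor of ~2.4. The package therefore reports both, and
null checks should use the raw-series value.

## Numerical choices and degenerate inputs

* Classifier scores of exactly 0 are assigned "aged" (measure-zero
  tie-break, documented rather than left to library internals).
* Zero-variance ROI columns are an error naming the ROI, not a silent
  `NaN`, protecting downstream counting.
* Spearman on a constant series is mathematically undefined; the package
  returns 0 with a warning.
* Constant (zero-s.d.) edges are left unscaled by the standardiser.
* Welch tests on two zero-variance samples with equal means return
  $t = 0, p = 1$; with unequal means they are an error.
* Empty filter results are returned as empty cohorts with a warning, not
  errors, so batch scripts can continue.
* All randomness (group subsampling, generator noise) flows through
  explicit integer seeds; identical config + seed reruns are
  byte-identical, and every output file embeds the config hash and seed.

## Problem sizes used in the test suite

The packaged tests and the acceptance script run the full pipeline on
cohorts of 400 subjects with 20 ROIs (190 edges) and 20 replicates per
stochastic check — sizes at which the SVM step is essentially instant
while every per-age cell still holds ≈ 4 subjects, reproducing the
small-cell noise that motivates the sliding window. The bookkeeping
checks (training/validation/test sizes) use the published per-group
subject counts directly, and so are exact at full cohort scale.

## Known limitations

* The hypothesis rule is one consistent formalisation of a narrative
  assignment; other thresholds could reproduce the same twelve labels.
* Spearman's $\rho_s$ measures monotone association only; genuinely
  nonlinear aging trajectories may be under-detected.
* No multi-site harmonisation (e.g. ComBat) is applied — site effects are
  addressed only by filtering, as in the reference analyses.
* The generator's effect sizes are calibration knobs, not estimates of
  real cohorts; no public effect-size estimates were available to anchor
  them.
* A single random subsample of the larger class is drawn per run (one
  draw is what the reference analyses report); repeat-and-aggregate
  robustness can be obtained by varying the seed.
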