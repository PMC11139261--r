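# connectomeAge

Does the resting-state functional connectome of a brain change
*monotonically* with age? `connectomeAge` implements a classification-based
answer: a linear support-vector machine is trained to separate the
connectivity patterns of two extreme age groups and is then asked to
classify subjects at intermediate ages it has never seen. If brain aging is
progressive, the percentage of subjects classified as "aged" should rise
steadily across the unseen interval.

The package is aimed at neuroimaging researchers working with ROI-level
rsfMRI data (time courses or precomputed Pearson-correlation features). It
starts downstream of preprocessing and parcellation: a subject's
connectivity pattern is the vector of R(R−1)/2 pairwise Pearson
correlations between its R ROI time courses.

## The method in brief

For group sizes N₁ (young) and N₂ (aged):

1. m = min(N₁, N₂); train a linear-kernel SVM (C = 1, per-edge
   standardisation) on all m subjects of the smaller group plus a seeded
   random m-subset of the larger — exactly balanced classes.
2. The k = max(N₁, N₂) − m left-out subjects give a validation accuracy
   rate (AR).
3. Classify every subject in the unseen test bins; tally the percent
   classified as aged at each integer age; smooth with a 5-year sliding
   window.
4. Fit OLS (intercept β₀ in percent, slope β₁ in percent/year, x = years
   since the youngest test age) and Spearman's ρₛ between age and the
   smoothed percentages; map (β₀, β₁, ρₛ) to a trajectory hypothesis
   H1 (monotone increase), H2 (low-intercept rise / inverted U) or H3
   (flat).

Three interval designs probe complementary questions: extremes-in,
middle-out (interval 1); train young, test old (interval 2); train old,
test young (interval 3).

A second analysis counts, per subject, the edges whose correlation
strictly exceeds a magnitude threshold (0.6 by default; 0.45 and 0.7 for
sensitivity), separately for positive and negative (anticorrelated)
edges, and Welch-tests each age decade — optionally per sex — against the
youngest group.

Because raw multi-site cohorts cannot be redistributed, a synthetic
generator (`generateCohort()`, `scenarioPreset()`) produces cohorts under
an additive Fisher-z edge model with age drift, age-dependent variance
and sex-modulated effects, so the full pipeline runs and is tested
without any external data.

## Worked example

```r
library(connectomeAge)

cc <- generateCohort(scenarioPreset("monotone", seed = 11))
binning <- AgeBinning(c("18-30", "31-40", "41-50", "51-60", "61-70", "71-85"),
                      c(18, 31, 41, 51, 61, 71),
                      c(30, 40, 50, 60, 70, 85))
runMonotonicity(cc, 1, binning, seed = 5)
#> MonotonicityResult [ cohort , interval 1 ]
#>   training size 80 (m = 40/class), residual k = 160, AR = 1.000
#>   test subjects: 160 over 38 ages
#>   smoothed (window 5): beta0 = -13.574, beta1 = 3.662, Spearman rho = 0.949
#>   raw:                 beta0 = -14.208, beta1 = 3.688, Spearman rho = 0.923
#>   selected hypothesis: H1
```

Reading the output: the classifier separated the extreme groups perfectly
(AR = 1), the percent-classified-aged series rises ~3.7 percentage points
per year from a below-zero fitted intercept, and the Spearman rank
correlation of 0.95 between age and the smoothed percentages selects H1 —
the monotone-aging hypothesis, as it should for a cohort simulated with a
linear age drift. A `"null"` preset cohort instead gives chance-level
AR ≈ 0.48 and raw-series ρₛ ≈ −0.26, selecting no trend.

The connection-count side:

```r
summarizeFC(cc, binning, threshold = 0.6, stratifySex = TRUE)
# one row per (age bin, stratum): mean/s.d. of positive, negative and
# total supra-threshold counts, Welch p-values vs the youngest bin
```

`runFullAnalysis(runConfig(...))` chains everything (all intervals, all
thresholds, optional site/eyes/sex filters) and writes a JSON summary plus
tidy CSVs; `inst/scripts/run_analysis.R` wraps it for the shell.

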