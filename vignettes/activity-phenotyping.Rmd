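---
title: "Activity phenotyping from wearable devices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity phenotyping from wearable devices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`actiphen` derives physical-activity phenotypes from consumer wearable data
in IBD cohorts and relates them to patient-reported outcomes (PROs). This
vignette is the package's account of the method: the model and its
assumptions, the tunable parameters, the synthetic cohort that stands in for
the restricted real data, the numerical choices, and what the package's
tests do and do not establish.

## The data model

The unit of raw data is a **device-day**: participant, date, device brand,
steps, distance (miles), moderate-to-vigorous physical activity (MVPA,
minutes), and activity calories (kcal). Any metric may be missing; none may
be negative; durations are bounded by the day (an "activity duration of 24
hours" is treated as sensor error). PROs arrive as biannual questionnaires:
six PROMIS T-score domains (anxiety, depression, pain interference, fatigue,
sleep disturbance, satisfaction with social roles; population mean 50, SD
10) plus the disease index matching the IBD subtype — SCDAI for Crohn
disease (< 150 remission, 150–219 mild, 220–450 moderate, > 450 severe;
no hard upper bound, values above 600 are accepted with a warning) or SCCAI
for ulcerative/indeterminate colitis (0–19; ≥ 2.5 active).

The unit of analysis is the **activity window**: the `window_days` days
strictly before a questionnaire's completion date (the completion day itself
is excluded — the window is what preceded the report). A day counts as
"used" when at least one activity metric is recorded; a window is eligible
when `days_used >= ceiling(min_coverage * window_days)` — with the defaults,
21 of 42 days, consecutive or not. Each feature is averaged over the days on
which that feature was observed. A 42-day window always contains exactly 30
weekdays and 12 weekend days, so weekday/weekend wear percentages have fixed
denominators; capacities are nevertheless computed from the actual calendar
so other window lengths behave correctly.

## Cleaning

Two passes, in order:

1. **Unrealistic values** are blanked cell-wise at hard physical bounds
   (MVPA ≥ 1440 min; steps > 200,000; distance > 150 miles; calories >
   20,000 kcal). The row survives; only the offending cell is removed, so a
   bad duration does not discard a valid step count.
2. **Tukey fences** per metric on the pooled cohort-wide daily values:
   quartiles by linear interpolation, fences at `Q1 − 1.5·IQR` and
   `Q3 + 1.5·IQR`, values outside blanked. Fences are pooled rather than
   per participant or per brand: the outlier model is "implausible for a
   human day", not "unusual for this person", and pooling is the
   conservative reading when nothing more specific is justified.

`clean_daily()` iterates the fence filter per metric until no value is
removed. A single pass is *not* idempotent — each removal shrinks the
recomputed IQR slightly, so a second pass over large data removes a little
more — whereas the fixed point is idempotent by construction: cleaning
cleaned data is exactly a no-op. On the default synthetic cohort the
iteration converges in 3–5 passes per metric.

One property worth stating precisely: for a roughly normal feature, Tukey
fences exclude ~0.7% of mass, and the test suite asserts < 1% removal for
steps, distance and calories on a homogeneous (single-phenotype) cohort.
MVPA minutes are exempted from that bound because they are zero-inflated —
a large fraction of genuine no-exercise days — which compresses the lower
quartile and tightens the fences; the filter then trims ~2% of the long
right tail. On the full three-phenotype mixture the filter also clips part
of the high-activity component's tail (its SD is by far the largest); this
is a property of pooled fences on heterogeneous cohorts, not a defect, but
it is why cluster centroids sit slightly below the planted means.

## Choosing the aggregation lag

The window length is not assumed; it is selected by `scan_lags()`. For each
candidate lag (1, 2, 4, 6, 8, 12, 24 weeks) eligible windows are rebuilt and
window-mean steps are rank-correlated (Spearman, average ranks for ties,
p from the t approximation `t = rho·sqrt((n−2)/(1−rho²))`) with SCDAI in the
CD subset and SCCAI in the UC/IC subset. The two indices must be combined
into one selection criterion; the package uses the subgroup-size-weighted
mean of the absolute correlations, reports both per-index values alongside,
and breaks ties toward the shorter lag (prefer the more parsimonious
window). Each (window, score) pair enters once; no within-person correlation
adjustment is applied, matching the source analyses' approach. Lags with
fewer than 10 eligible pairs in both subsets are skipped with a warning.

**Identifiability.** Whether the true lag is recoverable depends on the
signal geometry. When between-phenotype activity differences are large
relative to day-to-day noise, all sub-lags of the true window carry nearly
the full signal and the scan cannot distinguish 4 from 6 weeks. The package
therefore documents a designed identifiability experiment
(`lag_identifiability_config()`): phenotype step means 7000/8000/9000 with
daily SD 3500, no participant effect, and disease scores tightly linked to
phenotype (SCDAI means 220/140/60, SD 40; SCCAI 8/5/2, SD 1.5). An a priori
power calculation — short windows average away less of the `sd/sqrt(days)`
daily noise, longer windows dilute the 42 informative days with
phenotype-free ones — puts the expected correlation peak at 6 weeks with
margins of ~0.03–0.06 over the 4- and 8-week lags at ~1,200 questionnaires,
large against the paired sampling error of correlated scans. The test suite
requires recovery of the 6-week lag in at least 4 of 5 seeds under this
scenario.

## The clustering core

Clustering is the methodological heart of the package and is implemented
from first principles (`activity_kmeans()`); `stats::kmeans` appears only as
an independent cross-check idea in the oracles, never in the fit path.

* **Objective.** SSE (cluster scatter): the sum over clusters of squared
  Euclidean distances of points to their own centroid.
* **Seeding.** k-means++: first centroid uniform, each next drawn with
  probability proportional to squared distance to the nearest chosen
  centroid. `n_init = 10` independent restarts; the run with the lowest SSE
  wins (ties to the earlier run, for determinism).
* **Iteration.** Lloyd's alternation of nearest-centroid assignment and
  centroid mean update; `max_iter = 300`; convergence when the Frobenius
  norm of the centroid displacement falls below `tol = 1e-4`. Assignment
  ties break to the lowest cluster index. An empty cluster is reseeded at
  the point farthest from its current centroid — this strictly removes the
  largest single SSE contribution, so the SSE trace stays non-increasing,
  which the tests assert iteration by iteration.
* **Scaling.** Off by default: clustering runs on raw feature values
  (z-score and min-max are available behind `scale=`). With steps in the
  thousands, raw-scale Euclidean distance is dominated by steps; since the
  activity features are strongly correlated, scaling has little practical
  effect on cluster quality here, and raw values keep centroids directly
  interpretable.
* **Validation.** Silhouette coefficients: `a_x` the mean distance to the
  point's own cluster (excluding itself), `b_x` the smallest mean distance
  to another cluster, `s_x = (b_x − a_x)/max(a_x, b_x)`, with the singleton
  convention `s_x = 0`. K is scanned over 2–5 and chosen by the highest
  average silhouette (ties to the smaller K); an SSE elbow table
  (`sse_scan()`) is emitted for inspection. The feature subset is chosen by
  exhaustively evaluating every subset of size ≥ 2 of the six candidates
  (57 subsets) by the same criterion.
* **Labels.** With K = 3, clusters are ordered by ascending centroid steps
  into low / moderate / high physical activity; other K get ordinal
  `level_k` labels.
* **Determinism.** An explicit `seed` makes the fit bit-identical across
  runs; `seed = NULL` gives nondeterministic seeding from the session RNG.

The fit returns a classed S3 object with `print`, `summary`, `coef`
(raw-scale centroids), `predict` (nearest-centroid assignment of new
windows), `fitted`, `residuals` and `plot` methods.

## Association and transitions

Cross-sectionally (`profile_clusters()`), continuous variables get
per-cluster mean/SD and a one-way ANOVA; categorical variables get counts,
percentages and a Pearson chi-square (flagged when any expected count is
below 5). Disease indices are profiled within the matching IBD subtype only.
The unit is the window, so participants with several questionnaires
contribute several windows; no repeated-measures correction is applied —
this mirrors the published analyses and is a documented caveat, since
within-person correlation makes the nominal p-values anti-conservative.
Welch's correction and multiple-testing adjustment are likewise deliberately
absent (flag-switchable ANOVA; raw p at α = .05), matching the analyses
being reproduced.

Longitudinally (`pair_consecutive()`), questionnaires are paired within
participant when the gap falls in [90, 270] days — "biannual" with a
generous tolerance, config-exposed. Movement between clusters is classified
(same / adjacent up / adjacent down / extreme up / extreme down, extreme =
low ↔ high), and the paired change in the subtype's own disease score is
tested with a two-tailed paired t test, suppressed for cells with fewer than
5 pairs (small-cell reporting rule). Percentages are kept at full precision
internally and rounded to one decimal only in reports.

Degenerate statistical inputs follow explicit conventions rather than NaN:
all-identical ANOVA observations give F = 0, p = 1; zero within-group
variance with unequal means gives an infinite statistic, the smallest
representable p and a degeneracy flag; the paired t behaves analogously.
These branches are unit-tested.

## The synthetic cohort

Real cohorts of this kind are not publicly distributable, so
`generate_cohort()` is a first-class, tested module that plants the
structure the pipeline is meant to find. Defaults describe the emulated
study conditions: 430 participants (66.3% CD), ~3 questionnaires each
(rounded N(3, 2), min 1) spaced 182 ± 14 days, 42-day windows, wear
probability 37.3/42 per day, and three latent phenotypes with the published
per-phenotype feature moments (steps 5000.3/8229.5/12319.4 with SDs
1062.4/1033.0/1899.6, and analogous distance and MVPA moments), PRO moments
(e.g. fatigue 54.9/51.5/50.7), initial phenotype distribution
(0.337, 0.46, 0.203), and a 3×3 transition matrix whose rows are estimated
from the published pooled 6-month transition counts (overall self-transition
~68%, low ↔ high ~1.2%).

Design choices that were genuinely open:

* **Zero-censored draws with exact means.** Worn-day features draw from a
  normal censored at zero. Censoring biases the mean upward, severely so
  for MVPA (mean ≈ SD); the generator therefore solves
  `E[max(0, N(m, s))] = target` for the location `m` (one `uniroot` per
  phenotype × feature), so the marginal per-phenotype mean equals the
  configured value exactly. The tests assert the planted means to within 3
  standard errors on ≥ 400 windows per phenotype. A side effect is a
  realistic point mass of zero-MVPA days (~1/3 in the low phenotype).
* **Shared participant effect, scaled by phenotype SD.** A single N(0, 1)
  scalar per participant loads on every feature with SD
  `re_frac × (phenotype feature SD)`, default `re_frac = 0.70`. The shared
  scalar induces the strong cross-feature correlation seen in real wearable
  data (steps, distance and MVPA rank-correlate highly); scaling by the
  phenotype SD makes within-phenotype heterogeneity grow with activity
  level, reproducing the published pattern in which the high-activity
  cluster is the most variable and the low-activity cluster the most
  cohesive (highest silhouette). A flat, phenotype-independent loading was
  considered and rejected: it equalizes within-cluster spreads and inverts
  that silhouette ordering.
* **Days outside every window** draw from a phenotype-free baseline (the
  mixture mean with pooled SD), so activity is linked to disease state only
  within the pre-questionnaire window — the property the lag scan exploits.
* **Calories** are affine in steps (`47 + 0.06·steps` kcal) plus N(0, 40)
  noise, reproducing the observed overall calories mean/SD; they carry no
  independent phenotype signal.
* **Covariates** (age, BMI, disease duration, current treatments) are drawn
  from the published per-cluster moments keyed to the participant's initial
  phenotype; sociodemographics are cohort-level. Disease scores are floored
  at 0 (SCDAI) or clipped to [0, 19] (SCCAI).
* One global seed drives a single RNG stream; identical seeds give
  byte-identical CSV artifacts.

What the generator does **not** model — and what passing tests therefore do
not establish about real data: within-person day-to-day autocorrelation and
weekly rhythms (days are exchangeable within a window); device-brand
measurement bias; informative missingness (wear is Bernoulli, independent
of health state); dropout (every participant completes their scheduled
questionnaires, so the share with ≥ 2 consecutive questionnaires is higher
than in a real cohort); and seasonality. The planted clusters are also
somewhat cleaner than real ones: the recovered average silhouette (~0.7)
exceeds the published ~0.54, which is why cluster-recovery checks (adjusted
Rand index ≥ 0.8 against the planted truth) are a validation of the
pipeline's correctness, not a claim about attainable clustering quality in
the field.

## Problem sizes and budgets

The test suite and the acceptance script run the full default cohort (430
participants, ~1,250–1,350 eligible windows, ~200,000 device-days), the
moment-recovery check at 2,400 single-window participants, the lag
experiment at 5 seeds × ~1,290 questionnaires, type-I-error calibration at
1,000 null replicates per test, and the exhaustive k = 2 optimality check at
100 instances of n ≤ 8 — sizes chosen so each property is measured with
comfortable statistical margin while the whole suite stays fast.

## Known limitations

* ANOVA/chi-square p-values ignore repeated windows per participant (as
  published); a mixed-model alternative is out of scope.
* Pooled Tukey fences trim real structure on strongly heterogeneous
  cohorts; per-brand or per-person fences are not implemented.
* The lag scan's combined criterion (n-weighted mean absolute rho) is one
  reasonable resolution of an ambiguous choice; both per-index correlations
  are always reported so an analyst can apply a different rule.
* `movement` classification and transition summaries assume the three-level
  labeling; other K fall back to ordinal labels and are not classified into
  adjacent/extreme moves.
* No causal reading: the design is observational and the 6-month spacing
  precludes ordering activity changes against symptom changes.
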