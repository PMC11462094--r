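# actiphen

Digital physical-activity phenotyping from consumer wearable devices in
inflammatory bowel disease (IBD) cohorts, and its relationship with
patient-reported outcomes (PROs).

Patients with Crohn disease (CD) or ulcerative/indeterminate colitis (UC/IC)
in internet-based cohorts sync consumer wearables (Fitbit, Garmin, ...) and
complete biannual questionnaires: six PROMIS T-score domains (population mean
50, SD 10) plus a disease-activity index — the short Crohn Disease Activity
Index (SCDAI; < 150 remission, 150–219 mild, 220–450 moderate, > 450 severe)
or the Simple Clinical Colitis Activity Index (SCCAI; range 0–19, ≥ 2.5
active). `actiphen` is the analysis pipeline for such data: it turns noisy
device-day records into per-questionnaire activity windows, clusters them
into interpretable activity phenotypes, and quantifies how the phenotypes
relate to symptoms cross-sectionally and over time. It is aimed at
biostatisticians and mobile-health researchers working with
bring-your-own-device activity streams.

## The method

1. **Cleaning.** Physically impossible values are blanked (e.g. an activity
   duration of 24 h = 1440 min); each activity metric is then filtered by
   Tukey fences `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` on the pooled daily values,
   iterated to a fixed point so cleaning is idempotent.
2. **Windows.** For each questionnaire, daily features are averaged over the
   *w* = 42 days strictly before completion; a window is eligible when it has
   data on at least ⌈0.5 *w*⌉ days (consecutive or not). The lag *w* itself is
   selected by scanning Spearman correlations between window-mean steps and
   disease activity at lags of 1–24 weeks (`scan_lags()`).
3. **Clustering.** Windows are clustered on raw feature values by
   k-means++/Lloyd iterations minimizing the cluster scatter
   SSE = Σ_i Σ_{x ∈ C_i} dist(x, c_i)², with best-of-`n_init` restarts,
   tolerance-based convergence, and validation by silhouette coefficients
   s(x) = (b_x − a_x)/max(a_x, b_x). The feature subset and the number of
   clusters K (scanned over 2–5, plus an SSE elbow table) are chosen to
   maximize the average silhouette; clusters are labeled low / moderate /
   high by ascending centroid steps.
4. **Association.** Cluster profiles (per-window means/SDs, counts) are
   compared by one-way ANOVA and chi-square tests; disease indices are
   profiled within the matching IBD subtype only.
5. **Transitions.** Consecutive questionnaires (gap 90–270 days) are paired;
   movement between clusters is classified, and the paired change in disease
   score is tested with two-tailed paired t tests, suppressed for cells with
   n < 5.

Because the motivating cohort data are not public, the package ships a
first-class synthetic generator (`generate_cohort()`): three latent activity
phenotypes with published feature and PRO moments, ~88.8% wear-day coverage,
a shared participant effect inducing realistic cross-feature correlation, and
6-month phenotype persistence of ~68% via a Markov chain. Every downstream
stage is tested against this planted truth.

## Worked example

```r
library(actiphen)

co <- generate_cohort(cohort_config(n_participants = 150, seed = 1))
cleaned <- clean_daily(co$daily)
w <- build_windows(cleaned$records, co$questionnaires)
wear_summary(w)
#> Wear-time summary
#>   windows:        460
#>   days used:      37.1 (SD 2.6), 88.3% of window
#>   weekday wear:   88.3%
#>   weekend wear:   88.3%

feats <- c("mean_steps", "mean_distance_miles", "mean_mvpa_minutes")
w <- w[complete.cases(w[, feats]), ]
sel <- select_k(w[, feats], 2, 5, seed = 1)   # silhouette scan over K = 2..5
sel$k
#> [1] 3
fit <- label_clusters(sel$fit)
summary(fit)
#> Cluster profile
#>  cluster    label   n  pct silhouette mean_steps mean_distance_miles
#>        1 moderate 221 48.0      0.655     8300.3                 3.7
#>        2      low 153 33.3      0.780     5245.1                 2.2
#>        3     high  86 18.7      0.655    10740.5                 5.1
#>  mean_mvpa_minutes
#>               40.2
#>               20.9
#>               75.0
#> SSE: 163392219   average silhouette: 0.696
```

460 six-week windows pass the wear-time rule (37.1 of 42 days worn on
average). The silhouette scan picks K = 3; the three clusters are labeled by
ascending centroid steps, and the low-activity cluster is the most
homogeneous (silhouette 0.78). Against the generator's planted phenotypes
the recovered partition scores an adjusted Rand index of 0.855. Pairing
consecutive questionnaires:

```r
asg <- data.frame(participant_id = w$participant_id,
                  completion_date = w$completion_date,
                  label = as.character(fit$cluster_label))
summ <- summarize_transitions(pair_consecutive(co$questionnaires, asg))
summ$by_category
#>       category   n   percent
#>           same 210 67.961165
#>   low_moderate  54 17.475728
#>  moderate_high  40 12.944984
#>       low_high   5  1.618123
```

About 68% of consecutive periods stay in the same activity cluster, and
moves between the extreme clusters (low ↔ high) are rare — the persistence
structure the generator plants.

`run_pipeline(run_config(out_dir = "results", seed = 1))` executes all of
the above as one reproducible run, writing per-stage CSV/JSON artifacts and
a manifest with file digests (identical seed ⇒ identical digests).

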