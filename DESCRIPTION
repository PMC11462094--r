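Package: actiphen
Title: Physical Activity Phenotyping from Consumer Wearables in IBD Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Digital phenotyping of daily physical activity from consumer
    wearable devices in inflammatory bowel disease (IBD) cohorts. Cleans
    device-day activity records (unrealistic-value removal, Tukey fences),
    aggregates them into pre-questionnaire activity windows with wear-time
    eligibility, selects the aggregation lag by rank correlation with disease
    activity, derives low/moderate/high activity clusters with a hand-authored
    k-means++/Lloyd core validated by silhouette coefficients, and relates
    clusters to patient-reported outcomes cross-sectionally (one-way ANOVA,
    chi-square) and longitudinally (cluster-transition analysis with paired t
    tests and small-cell suppression). Includes a synthetic cohort generator
    with planted activity phenotypes and Markov phenotype dynamics so the full
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
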