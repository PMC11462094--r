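# Synthetic IBD wearable cohort with planted activity phenotypes.
#
# Emulates the statistical structure of the study cohort this pipeline is
# designed for: three latent activity phenotypes (low/moderate/high) with
# published feature moments, patient-reported outcome shifts per phenotype,
# ~88.8% wear-day coverage, and 6-month phenotype persistence of ~68% driven
# by a first-order Markov chain.

PHENOTYPES <- c("low", "moderate", "high")
CLUSTER_FEATURES <- c("steps", "distance_miles", "mvpa_minutes")

#' Default per-phenotype activity feature moments
#'
#' Mean and SD of daily steps, distance (miles) and moderate-to-vigorous
#' activity (minutes) for the low/moderate/high phenotypes, taken from the
#' published cluster profiles this generator emulates.
#'
#' @return List with `means` and `sds`, each a 3x3 matrix
#'   (phenotype x feature).
#' @export
default_cluster_params <- function() {
  means <- rbind(low      = c(5000.3, 2.2, 21.3),
                 moderate = c(8229.5, 3.7, 40.6),
                 high     = c(12319.4, 5.5, 73.0))
  sds <- rbind(low      = c(1062.4, 0.6, 27.0),
               moderate = c(1033.0, 0.7, 34.6),
               high     = c(1899.6, 1.1, 46.4))
  colnames(means) <- colnames(sds) <- CLUSTER_FEATURES
  list(means = means, sds = sds)
}

#' Default per-phenotype patient-reported outcome moments
#'
#' PROMIS T-score and disease-index (SCDAI/SCCAI) means and SDs per activity
#' phenotype, matching the published cross-sectional profiles: worst scores in
#' the low-activity phenotype, best in the high-activity phenotype.
#'
#' @return List with `means` and `sds`, each a 3x8 matrix (phenotype x score).
#' @export
default_pro_params <- function() {
  cols <- c(PROMIS_DOMAINS, "scdai", "sccai")
  means <- rbind(
    low      = c(50.4, 48.6, 50.7, 54.9, 51.2, 50.3, 133.3, 2.9),
    moderate = c(49.3, 47.1, 48.5, 51.5, 49.4, 54.0, 117.0, 2.6),
    high     = c(49.2, 46.9, 46.7, 50.7, 49.2, 55.3, 102.2, 2.3))
  sds <- rbind(
    low      = c(9.2, 8.3, 9.5, 10.7, 7.5, 9.7, 80.3, 2.1),
    moderate = c(8.9, 7.8, 8.4, 10.9, 7.7, 9.1, 71.9, 1.8),
    high     = c(8.9, 7.3, 7.6, 9.6, 7.8, 9.1, 59.7, 2.5))
  colnames(means) <- colnames(sds) <- cols
  list(means = means, sds = sds)
}

#' Default phenotype transition matrix
#'
#' Row-stochastic 3x3 matrix of 6-month phenotype transition probabilities,
#' with rows estimated from the published pooled transition counts (self
#' transitions ~68% overall, low<->high moves ~1.2%).
#'
#' @return 3x3 matrix, rows/columns `low`, `moderate`, `high`; rows sum to 1.
#' @export
default_transition_matrix <- function() {
  counts <- rbind(low      = c(175, 47, 1),
                  moderate = c(63, 216, 57),
                  high     = c(8, 58, 101))
  colnames(counts) <- PHENOTYPES
  counts / rowSums(counts)
}

#' Configure a synthetic wearable cohort
#'
#' Bundles and validates every parameter of [generate_cohort()]. Defaults
#' reproduce the emulated study's conditions: 430 participants (66.3% Crohn
#' disease), ~3 biannual questionnaires each, 6-week (42-day) activity windows
#' worn with probability 37.3/42, phenotype feature/PRO moments from
#' [default_cluster_params()] and [default_pro_params()], and phenotype
#' dynamics from [default_transition_matrix()].
#'
#' @param n_participants Number of participants.
#' @param cd_fraction Fraction with Crohn disease (the rest UC/IC).
#' @param q_mean,q_sd,q_min Questionnaires per participant: drawn as
#'   `max(q_min, round(N(q_mean, q_sd)))`.
#' @param spacing_days,spacing_jitter Days between consecutive questionnaires,
#'   plus a uniform jitter of up to `spacing_jitter` days either way.
#' @param window_days Length of the pre-questionnaire window during which
#'   daily activity is linked to the questionnaire's phenotype.
#' @param wear_prob Probability a given day has device data.
#' @param history_days Days of phenotype-free daily data generated before each
#'   participant's first questionnaire (supports lag scans up to 24 weeks).
#' @param cluster_params,pro_params Per-phenotype moments; see
#'   [default_cluster_params()], [default_pro_params()].
#' @param transition_matrix Row-stochastic 3x3 phenotype transition matrix.
#' @param init_dist Initial phenotype distribution.
#' @param re_frac Participant random-effect scale: a single shared
#'   participant scalar loads on every feature with SD
#'   `re_frac * (phenotype feature SD)`. The shared scalar induces the
#'   cross-feature correlation seen in real wearable data; scaling by the
#'   phenotype SD makes within-phenotype heterogeneity grow with the
#'   activity level, as in the emulated cluster profiles.
#' @param calories Affine calories model: `intercept + per_step * steps`
#'   plus Gaussian noise with SD `sd`.
#' @param miss_prob Probability a non-steps metric is missing on a worn day.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 430,
                          cd_fraction = 0.663,
                          q_mean = 3, q_sd = 2, q_min = 1,
                          spacing_days = 182, spacing_jitter = 14,
                          window_days = 42,
                          wear_prob = 37.3 / 42,
                          history_days = 168,
                          cluster_params = default_cluster_params(),
                          pro_params = default_pro_params(),
                          transition_matrix = default_transition_matrix(),
                          init_dist = c(low = 0.337, moderate = 0.46, high = 0.203),
                          re_frac = 0.70,
                          calories = c(intercept = 47, per_step = 0.06, sd = 40),
                          miss_prob = 0.02,
                          seed = 1) {
  cfg <- list(n_participants = as.integer(n_participants),
              cd_fraction = cd_fraction,
              q_mean = q_mean, q_sd = q_sd, q_min = as.integer(q_min),
              spacing_days = spacing_days, spacing_jitter = spacing_jitter,
              window_days = as.integer(window_days),
              wear_prob = wear_prob, history_days = as.integer(history_days),
              cluster_params = cluster_params, pro_params = pro_params,
              transition_matrix = transition_matrix,
              init_dist = init_dist / sum(init_dist),
              re_frac = re_frac, calories = calories,
              miss_prob = miss_prob, seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (!(cfg$wear_prob > 0 && cfg$wear_prob <= 1))
    stop("wear_prob must be in (0, 1]", call. = FALSE)
  tm <- cfg$transition_matrix
  if (is.null(tm) || !is.matrix(tm) || any(dim(tm) != 3) || any(tm < 0))
    stop("transition_matrix must be a non-negative 3x3 matrix", call. = FALSE)
  if (any(abs(rowSums(tm) - 1) > 1e-12))
    stop("transition_matrix rows must sum to 1", call. = FALSE)
  for (p in list(cfg$cluster_params, cfg$pro_params))
    if (any(p$sds <= 0)) stop("all SDs must be > 0", call. = FALSE)
  if (abs(sum(cfg$init_dist) - 1) > 1e-12 || any(cfg$init_dist < 0))
    stop("init_dist must be a probability vector", call. = FALSE)
  if (cfg$q_min < 1) stop("q_min must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic wearable cohort
#'
#' Simulates daily device records, biannual questionnaires, and the latent
#' phenotype truth behind them. Per participant, a phenotype sequence is drawn
#' from the configured Markov chain (one state per questionnaire); each day in
#' the `window_days` before a questionnaire is worn with probability
#' `wear_prob` and, when worn, draws its activity features from a zero-censored
#' normal whose location is calibrated so the censored marginal mean equals the
#' configured phenotype mean exactly. Days outside every window draw from a
#' phenotype-free baseline, so activity is linked to disease state only within
#' the pre-questionnaire window. A shared participant scalar shifts all
#' features, inducing within-person cross-feature correlation; calories are an
#' affine function of steps plus noise. PRO scores draw from the phenotype's
#' configured moments (SCDAI floored at 0; SCCAI clipped to `[0, 19]`).
#'
#' @param config A [cohort_config()].
#' @param seed Seed overriding `config$seed` (identical seed, identical output).
#' @return List of class `synthetic_cohort` with elements `daily`,
#'   `questionnaires`, `truth` (participant, questionnaire index, phenotype)
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_cohort_config(config)
  with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_participants
  pid <- sprintf("p%04d", seq_len(n))
  ibd <- ifelse(stats::runif(n) < cfg$cd_fraction, "CD", "UC_IC")
  brand <- sample(c("fitbit", "garmin", "jawbone", "under_armour"), n, TRUE,
                  prob = c(0.863, 0.100, 0.028, 0.009))
  z <- stats::rnorm(n)  # shared activity propensity
  start <- as.Date("2015-01-01") + sample.int(1461L, n, replace = TRUE) - 1L
  nq <- pmax(cfg$q_min, as.integer(round(stats::rnorm(n, cfg$q_mean, cfg$q_sd))))

  # latent phenotype chain, one state per questionnaire
  maxq <- max(nq)
  cumP <- t(apply(cfg$transition_matrix, 1, cumsum))
  ph <- matrix(NA_integer_, n, maxq)
  ph[, 1] <- sample.int(3L, n, TRUE, prob = cfg$init_dist)
  if (maxq > 1) for (t in 2:maxq) {
    act <- which(nq >= t)
    if (!length(act)) next
    u <- stats::runif(length(act))
    prev <- cumP[ph[act, t - 1], , drop = FALSE]
    ph[act, t] <- 1L + as.integer(rowSums(prev < u))
  }

  # questionnaire schedule
  pidx <- rep(seq_len(n), nq)
  qidx <- sequence(nq)
  jitter <- round(stats::runif(length(pidx), -cfg$spacing_jitter, cfg$spacing_jitter))
  qdate <- start[pidx] + cfg$history_days + (qidx - 1L) * cfg$spacing_days + jitter
  phq <- ph[cbind(pidx, qidx)]

  # PRO scores per questionnaire
  pm <- cfg$pro_params$means; ps <- cfg$pro_params$sds
  q <- data.frame(participant_id = pid[pidx],
                  completion_date = qdate,
                  ibd_type = ibd[pidx],
                  stringsAsFactors = FALSE)
  for (v in PROMIS_DOMAINS)
    q[[v]] <- round(stats::rnorm(nrow(q), pm[phq, v], ps[phq, v]), 1)
  scdai <- pmax(0, stats::rnorm(nrow(q), pm[phq, "scdai"], ps[phq, "scdai"]))
  sccai <- pmin(19, pmax(0, stats::rnorm(nrow(q), pm[phq, "sccai"], ps[phq, "sccai"])))
  q$scdai <- ifelse(q$ibd_type == "CD", round(scdai, 1), NA_real_)
  q$sccai <- ifelse(q$ibd_type == "UC_IC", round(sccai, 1), NA_real_)

  # participant covariates keyed to the initial phenotype (older, heavier,
  # longer disease duration in the low-activity phenotype)
  p1 <- ph[, 1]
  age <- round(pmax(18, stats::rnorm(n, c(45.8, 43.5, 42.1)[p1], c(13.8, 13.7, 12.6)[p1])), 1)
  bmi <- round(pmax(15, stats::rnorm(n, c(27.8, 25.6, 23.6)[p1], c(3.5, 4.5, 3.5)[p1])), 1)
  dur <- round(pmax(0, stats::rnorm(n, c(17.4, 16.9, 14.8)[p1], c(12.3, 12.0, 10.0)[p1])), 1)
  gender <- ifelse(stats::runif(n) < 0.74, "woman", "man")
  smoking <- ifelse(stats::runif(n) < 0.281, "ever", "never")
  education <- sample(c("high_school_or_less", "some_college", "college_or_more"),
                      n, TRUE, prob = c(0.050, 0.171, 0.779))
  cur <- function(p) stats::runif(n) < p[p1]
  cov_df <- data.frame(age = age, bmi = bmi, disease_duration_years = dur,
                       gender = gender, smoking = smoking, education = education,
                       current_5asa = cur(c(0.378, 0.315, 0.302)),
                       current_biologic = cur(c(0.596, 0.568, 0.553)),
                       current_corticosteroid = cur(c(0.113, 0.092, 0.024)),
                       current_immunomodulator = cur(c(0.243, 0.317, 0.290)),
                       stringsAsFactors = FALSE)
  q <- cbind(q, cov_df[pidx, , drop = FALSE])
  rownames(q) <- NULL

  # daily stream: history_days before the first questionnaire through the day
  # before the last one
  firstq <- qdate[qidx == 1L]            # in participant order
  lastq <- as.Date(as.numeric(tapply(as.numeric(qdate), factor(pidx, levels = seq_len(n)), max)),
                   origin = "1970-01-01")
  day0 <- firstq - cfg$history_days
  ndays <- as.integer(lastq - day0)
  dpidx <- rep(seq_len(n), ndays)
  ddate <- rep(day0, ndays) + (sequence(ndays) - 1L)
  worn <- stats::runif(length(ddate)) < cfg$wear_prob
  dpidx <- dpidx[worn]; ddate <- ddate[worn]
  nw <- length(ddate)

  # attribute each worn day to the next questionnaire when within its window
  key <- dpidx * 1e6 + as.numeric(ddate)
  qkey <- pidx * 1e6 + as.numeric(qdate)
  qord <- order(qkey)                    # guard against jitter reordering
  qkey <- qkey[qord]
  pidx <- pidx[qord]; qdate <- qdate[qord]; phq <- phq[qord]
  nxt <- findInterval(key, qkey) + 1L
  in_win <- nxt <= length(qkey) & pidx[nxt] == dpidx &
    (as.numeric(qdate[nxt]) - as.numeric(ddate)) <= cfg$window_days
  day_ph <- ifelse(in_win, phq[pmin(nxt, length(qkey))], 0L)  # 0 = baseline

  # censored-normal locations calibrated so marginal means match exactly.
  # The shared participant scalar z_i loads with SD = re_frac * (phenotype
  # feature SD): activity heterogeneity grows with the activity level, as in
  # the emulated cluster profiles (largest SDs in the high cluster).
  cm <- cfg$cluster_params$means; cs <- cfg$cluster_params$sds
  base_mean <- colSums(cfg$init_dist * cm)
  base_sd <- sqrt(colSums(cfg$init_dist * cs^2))
  loc <- matrix(NA_real_, 4, 3, dimnames = list(c(PHENOTYPES, "baseline"),
                                                CLUSTER_FEATURES))
  sdm <- rbind(cs, baseline = base_sd)
  marg_infl <- sqrt(1 + cfg$re_frac^2)
  for (f in CLUSTER_FEATURES) {
    for (p in 1:3)
      loc[p, f] <- censored_normal_location(cm[p, f], cs[p, f] * marg_infl)
    loc[4, f] <- censored_normal_location(base_mean[f], base_sd[f] * marg_infl)
  }
  row <- ifelse(day_ph == 0L, 4L, day_ph)
  feat <- matrix(NA_real_, nw, 3, dimnames = list(NULL, CLUSTER_FEATURES))
  for (f in CLUSTER_FEATURES)
    feat[, f] <- pmax(0, loc[row, f] +
                         sdm[row, f] * (cfg$re_frac * z[dpidx] +
                                        stats::rnorm(nw)))
  steps <- round(feat[, "steps"])
  calories <- round(pmax(0, cfg$calories[["intercept"]] +
                           cfg$calories[["per_step"]] * steps +
                           stats::rnorm(nw, 0, cfg$calories[["sd"]])), 1)
  daily <- data.frame(participant_id = pid[dpidx],
                      date = ddate,
                      brand = brand[dpidx],
                      steps = steps,
                      distance_miles = round(feat[, "distance_miles"], 3),
                      mvpa_minutes = round(feat[, "mvpa_minutes"], 1),
                      calories = calories,
                      stringsAsFactors = FALSE)
  if (cfg$miss_prob > 0)
    for (m in c("distance_miles", "mvpa_minutes", "calories"))
      daily[[m]][stats::runif(nw) < cfg$miss_prob] <- NA_real_

  truth <- data.frame(participant_id = pid[pidx],
                      q_index = qidx,
                      completion_date = qdate,
                      phenotype = PHENOTYPES[phq],
                      stringsAsFactors = FALSE)
  structure(list(daily = daily, questionnaires = q, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic wearable cohort\n")
  cat(sprintf("  participants:   %d (%.1f%% CD)\n",
              x$config$n_participants,
              pct(sum(tapply(x$questionnaires$ibd_type, x$questionnaires$participant_id,
                             function(v) v[1]) == "CD"), x$config$n_participants)))
  cat(sprintf("  questionnaires: %d\n", nrow(x$questionnaires)))
  cat(sprintf("  device-days:    %d\n", nrow(x$daily)))
  cat(sprintf("  phenotypes:     %s\n",
              paste(sprintf("%s %d", PHENOTYPES,
                            table(factor(x$truth$phenotype, PHENOTYPES))),
                    collapse = ", ")))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items, by the
#' standard pair-counting formula with the expected-index correction. Used to
#' score recovery of the planted phenotypes.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return ARI in `[-0.5, 1]`; 1 iff the partitions are identical up to label
#'   names, ~0 at chance level.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial and identical in pairs
  (sum_ij - expected) / denom
}
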