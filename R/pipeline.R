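# End-to-end orchestration: simulate (or load) -> validate -> preprocess ->
# lag scan -> feature-subset search -> cluster (K selection + labeling) ->
# cross-sectional association -> longitudinal transitions, writing one
# artifact per stage plus a run manifest with digests for reproducibility.

#' Configure a pipeline run
#'
#' @param out_dir Output directory for stage artifacts.
#' @param seed Integer seed driving the whole run.
#' @param daily_path,questionnaire_path Input CSVs; when `NULL`, a synthetic
#'   cohort is generated from `cohort` and written as the first stage.
#' @param cohort A [cohort_config()] used when inputs are not supplied.
#' @param window_days,min_coverage Window length and wear-time eligibility.
#' @param lags_weeks Candidate lags for [scan_lags()] (`NULL` to skip).
#' @param candidate_features Feature columns searched by
#'   [feature_subset_search()].
#' @param k Number of clusters; `NULL` selects K in `[2, 5]` by average
#'   silhouette via [select_k()].
#' @param n_init,max_iter,tol k-means parameters.
#' @param min_n Small-cell suppression threshold for paired t tests.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       daily_path = NULL, questionnaire_path = NULL,
                       cohort = NULL,
                       window_days = 42, min_coverage = 0.5,
                       lags_weeks = c(1, 2, 4, 6, 8, 12, 24),
                       candidate_features = c("mean_steps", "mean_distance_miles",
                                              "mean_mvpa_minutes", "mean_calories",
                                              "weekday_days_used", "weekend_days_used"),
                       k = NULL, n_init = 10, max_iter = 300, tol = 1e-4,
                       min_n = 5) {
  for (p in c(daily_path, questionnaire_path))
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p, call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 daily_path = daily_path, questionnaire_path = questionnaire_path,
                 cohort = cohort,
                 window_days = window_days, min_coverage = min_coverage,
                 lags_weeks = lags_weeks,
                 candidate_features = candidate_features,
                 k = k, n_init = n_init, max_iter = max_iter, tol = tol,
                 min_n = min_n),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full activity-phenotyping pipeline
#'
#' Executes every stage in order, writing each stage's artifact under
#' `config$out_dir` plus a `manifest.json` with the seed, per-stage row
#' counts and MD5 digests of every artifact. Identical config and seed give
#' byte-identical artifacts and therefore identical manifest digests. Any
#' stage failure aborts with the stage name and its error.
#'
#' @param config A [run_config()].
#' @return Object of class `actiphen_run`: the manifest plus in-memory stage
#'   results (`cohort`, `windows`, `model`, `profile`, `transitions`, ...).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)
  counts <- list()

  cohort <- NULL
  if (is.null(config$daily_path)) {
    cohort <- run_stage("simulate", {
      cc <- config$cohort %||% cohort_config(seed = config$seed)
      co <- generate_cohort(cc, seed = config$seed)
      write_daily_records(co$daily, art("daily.csv"))
      write_questionnaires(co$questionnaires, art("questionnaires.csv"))
      utils::write.csv(co$truth, art("truth.csv"), row.names = FALSE, quote = FALSE)
      co
    })
    config$daily_path <- art("daily.csv")
    config$questionnaire_path <- art("questionnaires.csv")
  }

  loaded <- run_stage("validate", {
    list(daily = read_daily_records(config$daily_path),
         questionnaires = read_questionnaires(config$questionnaire_path))
  })
  counts$daily_rows <- nrow(loaded$daily)
  counts$questionnaires <- nrow(loaded$questionnaires)

  prep <- run_stage("preprocess", {
    cleaned <- clean_daily(loaded$daily)
    windows <- build_windows(cleaned$records, loaded$questionnaires,
                             window_days = config$window_days,
                             min_coverage = config$min_coverage)
    report <- cleaned[c("n_rows_in", "n_unrealistic_removed",
                        "n_outliers_removed", "fences")]
    report$n_windows_built <- nrow(windows)
    report$n_windows_excluded_coverage <- attr(windows, "n_excluded_coverage")
    jsonlite::write_json(report, art("cleaning_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    win_out <- windows
    for (col in c("completion_date", "window_start", "window_end"))
      win_out[[col]] <- format(win_out[[col]], "%Y-%m-%d")
    utils::write.csv(win_out, art("windows.csv"), row.names = FALSE, quote = FALSE)
    list(records = cleaned$records, windows = windows, report = report)
  })
  counts$windows <- nrow(prep$windows)

  lag <- NULL
  if (!is.null(config$lags_weeks)) {
    lag <- run_stage("scan_lags", {
      ls <- suppressWarnings(scan_lags(prep$records, loaded$questionnaires,
                                       lags_weeks = config$lags_weeks,
                                       min_coverage = config$min_coverage))
      jsonlite::write_json(list(table = ls$table,
                                selected_lag_weeks = ls$selected_lag_weeks,
                                selected_significant = ls$selected_significant),
                           art("lag_scan.json"), auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", pretty = TRUE)
      ls
    })
  }

  # windows must be complete in every candidate feature to be clusterable
  cc <- stats::complete.cases(prep$windows[, config$candidate_features,
                                           drop = FALSE])
  prep$windows <- prep$windows[cc, , drop = FALSE]
  counts$windows_dropped_incomplete <- sum(!cc)
  counts$windows <- nrow(prep$windows)

  fsearch <- run_stage("select_features", {
    fs <- feature_subset_search(prep$windows,
                                candidate_features = config$candidate_features,
                                k = config$k %||% 3,
                                n_init = config$n_init,
                                max_iter = config$max_iter, tol = config$tol,
                                seed = config$seed)
    utils::write.csv(fs$ranking, art("feature_search.csv"),
                     row.names = FALSE, quote = FALSE)
    fs
  })

  model <- run_stage("cluster", {
    feats <- fsearch$best_features
    x <- prep$windows[, feats, drop = FALSE]
    if (is.null(config$k)) {
      sel <- select_k(x, 2, 5, n_init = config$n_init,
                      max_iter = config$max_iter, tol = config$tol,
                      seed = config$seed)
      k_used <- sel$k
      fit <- sel$fit
      diagnostics <- sel$diagnostics
    } else {
      k_used <- config$k
      fit <- activity_kmeans(x, k = k_used, n_init = config$n_init,
                             max_iter = config$max_iter, tol = config$tol,
                             seed = config$seed)
      diagnostics <- NULL
    }
    fit <- label_clusters(fit)
    jsonlite::write_json(list(k = k_used, features = feats,
                              centroids = as.data.frame(stats::coef(fit)),
                              labels = fit$labels, sse = fit$sse,
                              average_silhouette = fit$silhouette$average,
                              cluster_silhouettes = as.list(fit$silhouette$cluster_means),
                              k_selection = diagnostics),
                         art("model.json"), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    assignments <- data.frame(participant_id = prep$windows$participant_id,
                              completion_date = format(prep$windows$completion_date, "%Y-%m-%d"),
                              cluster = fit$cluster,
                              label = as.character(fit$cluster_label),
                              stringsAsFactors = FALSE)
    utils::write.csv(assignments, art("assignments.csv"),
                     row.names = FALSE, quote = FALSE)
    list(fit = fit, k = k_used, assignments = assignments,
         diagnostics = diagnostics)
  })
  counts$k <- model$k

  profile <- run_stage("associate", {
    pr <- profile_clusters(prep$windows, model$fit$cluster_label,
                           loaded$questionnaires)
    utils::write.csv(pr$continuous, art("profile.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(n = as.list(pr$n), continuous = pr$continuous),
                         art("profile.json"), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    pr
  })

  transitions <- run_stage("transitions", {
    asg <- model$assignments
    asg$completion_date <- as.Date(asg$completion_date)
    recs <- pair_consecutive(loaded$questionnaires, asg)
    if (nrow(recs)) {
      out <- recs
      out$date_from <- format(out$date_from, "%Y-%m-%d")
      out$date_to <- format(out$date_to, "%Y-%m-%d")
      utils::write.csv(out, art("transitions.csv"), row.names = FALSE, quote = FALSE)
      summ <- summarize_transitions(recs, min_n = config$min_n)
      jsonlite::write_json(list(total = summ$total,
                                by_category = summ$by_category,
                                by_cell = summ$by_cell),
                           art("transition_summary.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "rows", pretty = TRUE)
      list(records = recs, summary = summ)
    } else list(records = recs, summary = NULL)
  })
  counts$transition_pairs <- nrow(transitions$records)

  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
    digests <- as.list(tools::md5sum(file.path(config$out_dir, files)))
    names(digests) <- files
    man <- list(package = "actiphen",
                version = as.character(utils::packageVersion("actiphen")),
                seed = config$seed,
                window_days = config$window_days,
                counts = counts,
                artifacts = digests)
    jsonlite::write_json(man, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    man
  })

  structure(list(manifest = manifest, config = config, cohort = cohort,
                 windows = prep$windows, cleaning = prep$report,
                 lag_scan = lag, feature_search = fsearch,
                 model = model$fit, k = model$k,
                 k_diagnostics = model$diagnostics,
                 profile = profile, transitions = transitions),
            class = "actiphen_run")
}

#' @export
print.actiphen_run <- function(x, ...) {
  cat("actiphen pipeline run\n")
  cat(sprintf("  seed: %d   artifacts: %s\n", x$config$seed, x$config$out_dir))
  cnt <- x$manifest$counts
  cat(sprintf("  daily rows %d | questionnaires %d | windows %d | k %d | pairs %d\n",
              cnt$daily_rows, cnt$questionnaires, cnt$windows, cnt$k,
              cnt$transition_pairs))
  if (!is.null(x$lag_scan))
    cat(sprintf("  selected lag: %d week(s)\n", x$lag_scan$selected_lag_weeks))
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}
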