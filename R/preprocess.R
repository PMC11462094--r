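# Daily-record cleaning and aggregation into pre-questionnaire activity
# windows: unrealistic-value removal, cohort-wide Tukey fences per feature,
# wear-time eligibility (>= 50% of the window), and per-window feature means.

# hard physical bounds; a cell at/above its bound is blanked, the row kept
UNREALISTIC_BOUNDS <- c(steps = 200000, distance_miles = 150,
                        mvpa_minutes = 1440, calories = 20000)

#' Blank physically impossible metric values
#'
#' A metric cell is set missing when it violates a hard physical bound
#' (activity duration of a full 24 hours, i.e. `mvpa_minutes >= 1440`;
#' `steps > 200000`; `distance_miles > 150`; `calories > 20000`). The row is
#' retained; only the offending cell is removed.
#'
#' @param records Daily records ([read_daily_records()]).
#' @return List with `records` (cleaned) and `n_removed` (named count of
#'   blanked cells per metric).
#' @export
remove_unrealistic <- function(records) {
  n_removed <- stats::setNames(integer(length(ACTIVITY_METRICS)), ACTIVITY_METRICS)
  for (m in ACTIVITY_METRICS) {
    bad <- if (m == "mvpa_minutes") {
      !is.na(records[[m]]) & records[[m]] >= UNREALISTIC_BOUNDS[[m]]
    } else {
      !is.na(records[[m]]) & records[[m]] > UNREALISTIC_BOUNDS[[m]]
    }
    n_removed[[m]] <- sum(bad)
    records[[m]][bad] <- NA_real_
  }
  list(records = records, n_removed = n_removed)
}

#' Blank Tukey-fence outliers for one feature
#'
#' Computes the first and third quartiles of all non-missing daily values of
#' `feature` cohort-wide (quantiles by linear interpolation) and blanks values
#' outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. With fewer than 4 non-missing
#' values the call is a no-op with a warning.
#'
#' @param records Daily records.
#' @param feature One of `steps`, `distance_miles`, `mvpa_minutes`, `calories`.
#' @return List with `records`, `fences` (named length-2 vector) and
#'   `n_removed`.
#' @export
tukey_outlier_filter <- function(records, feature) {
  stopifnot(feature %in% ACTIVITY_METRICS)
  v <- records[[feature]]
  if (sum(!is.na(v)) < 4) {
    warning("fewer than 4 non-missing values of '", feature,
            "'; Tukey filter skipped", call. = FALSE)
    return(list(records = records,
                fences = c(lower = NA_real_, upper = NA_real_), n_removed = 0L))
  }
  qs <- stats::quantile(v, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  fences <- c(lower = qs[1] - 1.5 * iqr, upper = qs[2] + 1.5 * iqr)
  bad <- !is.na(v) & (v < fences[["lower"]] | v > fences[["upper"]])
  records[[feature]][bad] <- NA_real_
  list(records = records, fences = fences, n_removed = sum(bad))
}

#' Clean daily records
#'
#' Full cleaning pass: [remove_unrealistic()] followed by
#' [tukey_outlier_filter()] on each activity metric (cohort-wide, pooled
#' daily values), iterated per metric until the fences stabilize (no further
#' removals). Running the filter to its fixed point makes the cleaning
#' exactly idempotent: a second `clean_daily()` of its own output removes
#' nothing. Iteration converges in a handful of passes on realistic data;
#' `max_passes` is a safety bound.
#'
#' @param records Daily records.
#' @param tukey_features Metrics to pass through the Tukey filter.
#' @param max_passes Upper bound on fence-recomputation passes per metric.
#' @return List of class `cleaning_report` with `records` plus the counts:
#'   `n_rows_in`, `n_unrealistic_removed` (per metric),
#'   `n_outliers_removed` (per metric, summed over passes) and `fences`
#'   (per metric, from the final pass).
#' @export
clean_daily <- function(records, tukey_features = ACTIVITY_METRICS,
                        max_passes = 50) {
  n_in <- nrow(records)
  step1 <- remove_unrealistic(records)
  rec <- step1$records
  n_out <- stats::setNames(integer(length(tukey_features)), tukey_features)
  fences <- list()
  for (f in tukey_features) {
    for (pass in seq_len(max_passes)) {
      res <- tukey_outlier_filter(rec, f)
      rec <- res$records
      n_out[[f]] <- n_out[[f]] + res$n_removed
      fences[[f]] <- res$fences
      if (res$n_removed == 0) break
    }
  }
  structure(list(records = rec,
                 n_rows_in = n_in,
                 n_unrealistic_removed = step1$n_removed,
                 n_outliers_removed = n_out,
                 fences = fences),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Daily-record cleaning report\n")
  cat(sprintf("  rows in:              %d\n", x$n_rows_in))
  cat(sprintf("  unrealistic blanked:  %s\n",
              paste(sprintf("%s %d", names(x$n_unrealistic_removed),
                            x$n_unrealistic_removed), collapse = ", ")))
  cat(sprintf("  Tukey blanked:        %s\n",
              paste(sprintf("%s %d", names(x$n_outliers_removed),
                            x$n_outliers_removed), collapse = ", ")))
  invisible(x)
}

#' Aggregate daily records into pre-questionnaire activity windows
#'
#' For each questionnaire, takes the `window_days` days strictly before the
#' completion date, counts days with any recorded metric (`days_used`, split
#' into weekday/weekend, weekend = Saturday/Sunday), and averages each feature
#' over the days on which it was observed. Windows with
#' `days_used < ceiling(min_coverage * window_days)` are excluded (the
#' wear-time eligibility rule: at least 50% of days, consecutive or not);
#' the excluded count is available as `attr(x, "n_excluded_coverage")`.
#'
#' @param records Cleaned daily records.
#' @param questionnaires Questionnaires ([read_questionnaires()]).
#' @param window_days Window length in days (default 42 = 6 weeks).
#' @param min_coverage Minimum fraction of window days with data.
#' @return Data frame of eligible windows: ids/dates, `days_used`,
#'   `weekday_days_used`, `weekend_days_used`, capacities, and
#'   `mean_steps`, `mean_distance_miles`, `mean_mvpa_minutes`,
#'   `mean_calories`. Attributes `n_excluded_coverage`, `window_days`.
#' @export
build_windows <- function(records, questionnaires, window_days = 42,
                          min_coverage = 0.5) {
  stopifnot(window_days >= 1, min_coverage > 0, min_coverage <= 1)
  need <- ceiling(min_coverage * window_days)
  q <- questionnaires[order(questionnaires$participant_id,
                            questionnaires$completion_date), , drop = FALSE]
  recs <- split(records, records$participant_id)
  nq <- nrow(q)
  out <- data.frame(
    participant_id = q$participant_id,
    completion_date = q$completion_date,
    window_start = q$completion_date - window_days,
    window_end = q$completion_date - 1,
    days_used = 0L, weekday_days_used = 0L, weekend_days_used = 0L,
    weekday_capacity = 0L, weekend_capacity = 0L,
    mean_steps = NA_real_, mean_distance_miles = NA_real_,
    mean_mvpa_minutes = NA_real_, mean_calories = NA_real_,
    stringsAsFactors = FALSE)

  # per participant: sorted dates + cumulative sums give O(1) window queries
  for (pid in unique(q$participant_id)) {
    rows <- which(q$participant_id == pid)
    r <- recs[[pid]]
    if (is.null(r) || nrow(r) == 0) next
    r <- r[order(r$date), , drop = FALSE]
    dts <- as.numeric(r$date)
    used <- rowSums(!is.na(r[ACTIVITY_METRICS])) > 0
    wend <- format(r$date, "%u") %in% c("6", "7")
    cum_used <- cumsum(used)
    cum_wend <- cumsum(used & wend)
    cum_val <- lapply(ACTIVITY_METRICS, function(m) {
      x <- r[[m]]
      list(sum = cumsum(ifelse(is.na(x), 0, x)), n = cumsum(!is.na(x)))
    })
    names(cum_val) <- ACTIVITY_METRICS
    for (i in rows) {
      lohi <- findInterval(c(as.numeric(out$window_start[i]) - 0.5,
                             as.numeric(out$window_end[i]) + 0.5), dts)
      a <- lohi[1]; b <- lohi[2]
      if (b <= a) next
      span <- function(v) v[b] - if (a > 0) v[a] else 0
      out$days_used[i] <- span(cum_used)
      out$weekend_days_used[i] <- span(cum_wend)
      out$weekday_days_used[i] <- out$days_used[i] - out$weekend_days_used[i]
      for (m in ACTIVITY_METRICS) {
        nm <- span(cum_val[[m]]$n)
        out[[paste0("mean_", m)]][i] <-
          if (nm > 0) span(cum_val[[m]]$sum) / nm else NA_real_
      }
    }
  }
  # calendar capacity of each window (a 42-day window always has 30/12)
  wd <- weekend_days_in_range(out$window_start, out$window_end)
  out$weekend_capacity <- wd
  out$weekday_capacity <- window_days - wd

  eligible <- out$days_used >= need
  res <- out[eligible, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded_coverage") <- sum(!eligible)
  attr(res, "window_days") <- as.integer(window_days)
  res
}

# number of Saturdays/Sundays in [start, end], vectorized
weekend_days_in_range <- function(start, end) {
  len <- as.integer(end - start) + 1L
  full <- len %/% 7L
  rem <- len %% 7L
  dow <- as.integer(format(start, "%u"))  # 1 = Monday
  extra <- integer(length(start))
  for (i in seq_along(start)) {
    if (rem[i] > 0) {
      days <- ((dow[i] - 1L + seq_len(rem[i]) - 1L) %% 7L) + 1L
      extra[i] <- sum(days >= 6L)
    }
  }
  full * 2L + extra
}

#' Summarize wear-time across activity windows
#'
#' Mean and SD of days used per window, and wear percentages: overall
#' (mean days used over window length), weekday (mean weekday days used over
#' mean weekday capacity) and weekend analogously.
#'
#' @param windows Windows from [build_windows()].
#' @return List of class `wear_summary` with `n_windows`, `mean_days_used`,
#'   `sd_days_used`, `pct_of_window`, `weekday_pct`, `weekend_pct`
#'   (percentages at full precision; print rounds to one decimal).
#' @export
wear_summary <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0)
    stop("wear_summary requires at least one window", call. = FALSE)
  window_len <- mean(as.numeric(windows$window_end - windows$window_start) + 1)
  structure(list(
    n_windows = nrow(windows),
    mean_days_used = mean(windows$days_used),
    sd_days_used = stats::sd(windows$days_used),
    pct_of_window = pct(mean(windows$days_used), window_len, digits = NULL),
    weekday_pct = pct(mean(windows$weekday_days_used),
                      mean(windows$weekday_capacity), digits = NULL),
    weekend_pct = pct(mean(windows$weekend_days_used),
                      mean(windows$weekend_capacity), digits = NULL)),
    class = "wear_summary")
}

#' @export
print.wear_summary <- function(x, ...) {
  cat("Wear-time summary\n")
  cat(sprintf("  windows:        %d\n", x$n_windows))
  cat(sprintf("  days used:      %.1f (SD %.1f), %.1f%% of window\n",
              x$mean_days_used, x$sd_days_used, x$pct_of_window))
  cat(sprintf("  weekday wear:   %.1f%%\n", round(x$weekday_pct, 1)))
  cat(sprintf("  weekend wear:   %.1f%%\n", round(x$weekend_pct, 1)))
  invisible(x)
}
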