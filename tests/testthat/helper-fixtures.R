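# Shared in-code fixtures for the test suite.

daily_csv_text <- function(rows) {
  paste(c("participant_id,date,brand,steps,distance_miles,mvpa_minutes,calories",
          rows), collapse = "\n")
}

write_daily_csv <- function(rows) {
  path <- withr_local_tempfile()
  writeLines(daily_csv_text(rows), path)
  path
}

withr_local_tempfile <- function() {
  path <- tempfile(fileext = ".csv")
  path
}

# minimal questionnaire data frame (covariates optional)
make_questionnaires <- function(ids, dates, ibd_type = "CD",
                                scdai = NA_real_, sccai = NA_real_) {
  n <- length(ids)
  df <- data.frame(participant_id = ids,
                   completion_date = as.Date(dates),
                   ibd_type = rep_len(ibd_type, n),
                   stringsAsFactors = FALSE)
  for (v in actiphen::PROMIS_DOMAINS) df[[v]] <- 50
  df$scdai <- rep_len(scdai, n)
  df$sccai <- rep_len(sccai, n)
  df
}

# daily records at constant metric values over given dates
make_daily <- function(id, dates, steps = 7000, distance = 3, mvpa = 40,
                       calories = 450, brand = "fitbit") {
  data.frame(participant_id = id, date = as.Date(dates), brand = brand,
             steps = steps, distance_miles = distance, mvpa_minutes = mvpa,
             calories = calories, stringsAsFactors = FALSE)
}

# three well-separated planted blobs in 3 features, for cluster tests
make_blob_windows <- function(n_per = 60, seed = 1, calories_noise = TRUE) {
  set.seed(seed)
  centers <- rbind(c(5000, 2.2, 21), c(8200, 3.7, 41), c(12300, 5.5, 73))
  lab <- rep(1:3, each = n_per)
  x <- data.frame(
    mean_steps = centers[lab, 1] + rnorm(3 * n_per, 0, 400),
    mean_distance_miles = centers[lab, 2] + rnorm(3 * n_per, 0, 0.2),
    mean_mvpa_minutes = centers[lab, 3] + rnorm(3 * n_per, 0, 8))
  if (calories_noise)
    x$mean_calories <- rnorm(3 * n_per, 500, 100)  # independent of structure
  attr(x, "truth") <- lab
  x
}

# link windows back to the generating truth labels
truth_for_windows <- function(cohort, windows) {
  key <- paste(windows$participant_id, windows$completion_date)
  tkey <- paste(cohort$truth$participant_id, cohort$truth$completion_date)
  cohort$truth$phenotype[match(key, tkey)]
}
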