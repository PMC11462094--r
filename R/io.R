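# Data model: daily wearable records, questionnaire responses, disease-activity
# bands, and the CSV interchange formats used by every pipeline stage.

DAILY_COLUMNS <- c("participant_id", "date", "brand", "steps",
                   "distance_miles", "mvpa_minutes", "calories")
ACTIVITY_METRICS <- c("steps", "distance_miles", "mvpa_minutes", "calories")
DEVICE_BRANDS <- c("fitbit", "garmin", "jawbone", "under_armour", "other")

#' PROMIS domains carried on every questionnaire
#'
#' Column names of the six PROMIS T-score domains (population mean 50, SD 10).
#' @export
PROMIS_DOMAINS <- c("promis_anxiety", "promis_depression",
                    "promis_pain_interference", "promis_fatigue",
                    "promis_sleep_disturbance", "promis_social_satisfaction")

QUESTIONNAIRE_CORE <- c("participant_id", "completion_date", "ibd_type",
                        PROMIS_DOMAINS, "scdai", "sccai")

parse_iso_date <- function(x, what = "date") {
  out <- rep(as.Date(NA), length(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  bad <- which(!ok | is.na(out))
  if (length(bad))
    row_error(bad[1], "malformed ", what, " '", x[bad[1]], "' (ISO-8601 required)")
  out
}

parse_metric <- function(x, name, allow_negative = FALSE) {
  x <- trimws(x)
  out <- rep(NA_real_, length(x))
  filled <- !is.na(x) & nzchar(x)
  suppressWarnings(out[filled] <- as.numeric(x[filled]))
  bad <- which(filled & is.na(out))
  if (length(bad))
    row_error(bad[1], "non-numeric value '", x[bad[1]], "' in column '", name, "'")
  if (!allow_negative) {
    neg <- which(out < 0)
    if (length(neg))
      row_error(neg[1], "negative value ", out[neg[1]], " in column '", name, "'")
  }
  out
}

#' Read daily wearable activity records
#'
#' Reads a CSV of one-device-day activity records. The header must be exactly
#' `participant_id,date,brand,steps,distance_miles,mvpa_minutes,calories`,
#' dates ISO-8601, metrics non-negative; empty cells become missing values and
#' row order is preserved. Malformed dates or negative metrics raise an error
#' naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` with typed columns (`date` as `Date`, metrics numeric).
#' @seealso [write_daily_records()] for the inverse operation.
#' @export
read_daily_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(df), DAILY_COLUMNS))
    stop("daily records header must be exactly: ",
         paste(DAILY_COLUMNS, collapse = ","), call. = FALSE)
  brand <- tolower(trimws(df$brand))
  brand[!brand %in% DEVICE_BRANDS] <- "other"
  out <- data.frame(
    participant_id = df$participant_id,
    date = parse_iso_date(df$date),
    brand = brand,
    stringsAsFactors = FALSE
  )
  for (m in ACTIVITY_METRICS) out[[m]] <- parse_metric(df[[m]], m)
  out
}

#' Write daily wearable activity records
#'
#' Inverse of [read_daily_records()]: writes the exact CSV schema, missing
#' metrics as empty cells, numerics at full precision so a write/read
#' round-trip reproduces every field.
#'
#' @param records Data frame as returned by [read_daily_records()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_daily_records <- function(records, path) {
  stopifnot(all(DAILY_COLUMNS %in% names(records)))
  out <- records[DAILY_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  for (m in ACTIVITY_METRICS) out[[m]] <- format_num(out[[m]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

# full-precision numeric formatting for CSV round-trips
format_num <- function(x) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v)
    if (v == round(v) && abs(v) < 1e15) sprintf("%.0f", v) else sprintf("%.17g", v),
    character(1))
  out
}

#' Read biannual questionnaire responses
#'
#' Reads patient-reported outcome questionnaires: one row per completion, with
#' the six PROMIS T-scores, the disease index matching the IBD type (SCDAI for
#' Crohn disease, SCCAI for ulcerative/indeterminate colitis) and any
#' sociodemographic/clinical covariate columns. Rows are returned sorted by
#' `(participant_id, completion_date)`.
#'
#' Validation: duplicate `(participant_id, completion_date)` pairs and SCCAI
#' values outside `[0, 19]` are errors; SCDAI values above 600 are accepted
#' with a warning (the index has no hard upper bound); a filled disease index
#' that does not match `ibd_type` draws a warning.
#'
#' @param path Path to a CSV file.
#' @return A `data.frame`, sorted, with `completion_date` as `Date`.
#' @export
read_questionnaires <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(QUESTIONNAIRE_CORE, names(df))
  if (length(missing_cols))
    stop("questionnaire file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$completion_date <- parse_iso_date(df$completion_date, "completion_date")
  bad_type <- which(!df$ibd_type %in% c("CD", "UC_IC"))
  if (length(bad_type))
    row_error(bad_type[1], "ibd_type must be 'CD' or 'UC_IC', got '",
              df$ibd_type[bad_type[1]], "'")
  for (v in c(PROMIS_DOMAINS, "scdai", "sccai"))
    df[[v]] <- parse_metric(df[[v]], v)
  numeric_covs <- intersect(c("age", "bmi", "disease_duration_years"), names(df))
  for (v in numeric_covs) df[[v]] <- parse_metric(df[[v]], v)
  bad_sccai <- which(df$sccai < 0 | df$sccai > 19)
  if (length(bad_sccai))
    row_error(bad_sccai[1], "sccai value ", df$sccai[bad_sccai[1]],
              " outside [0, 19]")
  if (any(df$scdai > 600, na.rm = TRUE))
    warning("SCDAI value(s) above 600 accepted (index has no hard upper bound)",
            call. = FALSE)
  key <- paste(df$participant_id, df$completion_date)
  if (anyDuplicated(key))
    row_error(which(duplicated(key))[1],
              "duplicate (participant_id, completion_date) pair")
  mismatch <- (df$ibd_type == "CD" & !is.na(df$sccai)) |
    (df$ibd_type == "UC_IC" & !is.na(df$scdai))
  if (any(mismatch))
    warning(sum(mismatch),
            " questionnaire(s) carry the disease index of the other IBD type",
            call. = FALSE)
  df <- df[order(df$participant_id, df$completion_date), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write questionnaire responses
#'
#' @param questionnaires Data frame as returned by [read_questionnaires()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_questionnaires <- function(questionnaires, path) {
  out <- questionnaires
  out$completion_date <- format(out$completion_date, "%Y-%m-%d")
  num <- vapply(out, is.numeric, logical(1))
  for (v in names(out)[num]) out[[v]] <- format_num(out[[v]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Classify disease activity from an index score
#'
#' Maps an SCDAI or SCCAI score to its clinical activity band. SCDAI: `< 150`
#' remission, `150-219` mild, `220-450` moderate, `> 450` severe. SCCAI:
#' `< 2.5` remission, `>= 2.5` active.
#'
#' @param index `"SCDAI"` or `"SCCAI"`.
#' @param score Numeric score(s), non-negative.
#' @return Character vector of bands; SCDAI bands are
#'   `remission`/`mild`/`moderate`/`severe`, SCCAI bands `remission`/`active`.
#' @export
#' @examples
#' classify_disease_activity("SCDAI", c(133.3, 150, 220, 451))
#' classify_disease_activity("SCCAI", c(2.3, 2.5))
classify_disease_activity <- function(index, score) {
  if (length(index) != 1L || !toupper(index) %in% c("SCDAI", "SCCAI"))
    stop("index must be 'SCDAI' or 'SCCAI'", call. = FALSE)
  stopifnot(is.numeric(score))
  if (any(score < 0, na.rm = TRUE)) stop("score must be >= 0", call. = FALSE)
  if (toupper(index) == "SCDAI") {
    ifelse(score < 150, "remission",
      ifelse(score <= 219, "mild",
        ifelse(score <= 450, "moderate", "severe")))
  } else {
    ifelse(score < 2.5, "remission", "active")
  }
}

#' Is a disease-activity band active disease?
#'
#' @param band Band as returned by [classify_disease_activity()].
#' @return Logical: `TRUE` for any band other than remission.
#' @export
is_active_disease <- function(band) band != "remission"
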