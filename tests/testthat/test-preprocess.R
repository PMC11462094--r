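test_that("unrealistic values are blanked cell-wise at the physical bounds", {
  rec <- make_daily("p1", as.Date("2019-01-01") + 0:4)
  rec$mvpa_minutes <- c(1440, 1439, 40, 2000, NA)
  rec$steps <- c(8000, 200001, 200000, 10, 10)
  rec$distance_miles <- c(150.5, 150, 3, 3, 3)
  rec$calories <- c(20001, 20000, 400, 400, 400)
  out <- remove_unrealistic(rec)
  expect_equal(out$records$mvpa_minutes, c(NA, 1439, 40, NA, NA))
  expect_equal(out$records$steps, c(8000, NA, 200000, 10, 10))
  expect_equal(out$records$distance_miles, c(NA, 150, 3, 3, 3))
  expect_equal(out$records$calories, c(NA, 20000, 400, 400, 400))
  expect_equal(unname(out$n_removed),
               c(1L, 1L, 2L, 1L))  # steps, distance, mvpa, calories
  # rows are retained, only cells blanked
  expect_equal(nrow(out$records), 5)
})

test_that("Tukey filter blanks values outside the interpolated fences", {
  rec <- make_daily("p1", as.Date("2019-01-01") + 0:9)
  rec$steps <- c(1:9, 1000)
  out <- tukey_outlier_filter(rec, "steps")
  expect_equal(unname(out$fences), unname(oracle_tukey_fences(c(1:9, 1000))))
  expect_equal(out$n_removed, 1L)
  expect_true(is.na(out$records$steps[10]))
  expect_equal(out$records$steps[1:9], as.numeric(1:9))
})

test_that("Tukey filter removes nothing on constant data, warns below n = 4", {
  rec <- make_daily("p1", as.Date("2019-01-01") + 0:9, steps = 5000)
  out <- tukey_outlier_filter(rec, "steps")
  expect_equal(out$n_removed, 0L)
  rec3 <- make_daily("p1", as.Date("2019-01-01") + 0:2)
  expect_warning(out3 <- tukey_outlier_filter(rec3, "steps"), "fewer than 4")
  expect_equal(out3$records$steps, rec3$steps)
})

test_that("Tukey removals are tail-symmetric on symmetric data", {
  set.seed(8)
  base <- rnorm(200)
  vals <- 5000 + 500 * c(base, -base, 6, -6, 7, -7)  # symmetric incl. outliers
  rec <- make_daily("p1", as.Date("2015-01-01") + seq_along(vals) - 1,
                    steps = vals)
  out <- tukey_outlier_filter(rec, "steps")
  removed <- vals[is.na(out$records$steps)]
  expect_gt(length(removed), 0)
  expect_equal(sum(removed > 5000), sum(removed < 5000))
})

test_that("Tukey filter removes under 1% on a homogeneous cohort", {
  cfg <- cohort_config(n_participants = 60, q_mean = 2, q_sd = 0,
                       init_dist = c(low = 1, moderate = 0, high = 0),
                       transition_matrix = diag(3), seed = 13)
  co <- generate_cohort(cfg)
  rep <- clean_daily(co$daily)
  n_vals <- vapply(c("steps", "distance_miles", "mvpa_minutes", "calories"),
                   function(m) sum(!is.na(co$daily[[m]])), numeric(1))
  frac <- rep$n_outliers_removed / n_vals
  # the <1% tail property holds for the near-normal features; MVPA minutes
  # are zero-inflated (many genuine no-exercise days), which tightens the
  # fences and legitimately trims more of the long right tail
  for (m in c("steps", "distance_miles", "calories"))
    expect_lt(frac[[m]], 0.01, label = m)
  expect_lt(frac[["mvpa_minutes"]], 0.03)
})

test_that("cleaning is idempotent and order-invariant", {
  co <- generate_cohort(cohort_config(n_participants = 25, seed = 17))
  once <- clean_daily(co$daily)
  twice <- clean_daily(once$records)
  expect_identical(twice$records, once$records)
  # shuffled input rows leave every window identical
  set.seed(1)
  shuf <- co$daily[sample(nrow(co$daily)), ]
  w1 <- build_windows(clean_daily(co$daily)$records, co$questionnaires)
  w2 <- build_windows(clean_daily(shuf)$records, co$questionnaires)
  expect_equal(w2, w1, ignore_attr = TRUE)
})

test_that("windows apply the 50% wear-time eligibility rule", {
  q <- make_questionnaires("p1", "2019-03-01", scdai = 100)
  # 21 of 42 days = ceiling(0.5 * 42): eligible at the boundary
  rec21 <- make_daily("p1", as.Date("2019-03-01") - seq_len(21))
  w <- build_windows(rec21, q)
  expect_equal(nrow(w), 1)
  expect_equal(w$days_used, 21)
  expect_equal(attr(w, "n_excluded_coverage"), 0L)
  # 20 of 42 days: excluded
  rec20 <- make_daily("p1", as.Date("2019-03-01") - seq_len(20))
  w20 <- build_windows(rec20, q)
  expect_equal(nrow(w20), 0)
  expect_equal(attr(w20, "n_excluded_coverage"), 1L)
  # a questionnaire with no overlapping records is excluded, not an error
  w0 <- build_windows(make_daily("p1", "2010-01-01"), q)
  expect_equal(nrow(w0), 0)
})

test_that("window means cover observed days only and window edges are strict", {
  q <- make_questionnaires("p1", "2019-03-01", scdai = 100)
  # sparse wear: every other day, constant 7000 steps
  days <- as.Date("2019-03-01") - seq(1, 42, by = 2)
  rec <- make_daily("p1", days, steps = 7000)
  rec$distance_miles[1] <- NA  # feature means use each feature's own days
  w <- build_windows(rec, q)
  expect_equal(w$mean_steps, 7000)
  expect_equal(w$mean_distance_miles, 3)
  # completion day itself and day -43 are outside the window
  edge <- rbind(make_daily("p1", as.Date("2019-03-01"), steps = 1e5),
                make_daily("p1", as.Date("2019-03-01") - 43, steps = 1e5),
                make_daily("p1", as.Date("2019-03-01") - c(1, 42), steps = 7000),
                make_daily("p1", as.Date("2019-03-01") - 2:20, steps = 7000))
  we <- build_windows(edge, q)
  expect_equal(we$mean_steps, 7000)
  expect_equal(we$days_used, 21)
})

test_that("weekday/weekend splits follow the calendar", {
  q <- make_questionnaires("p1", "2019-03-04", scdai = 100)  # a Monday
  rec <- make_daily("p1", as.Date("2019-03-04") - seq_len(42))
  w <- build_windows(rec, q)
  expect_equal(w$weekday_capacity, 30)
  expect_equal(w$weekend_capacity, 12)
  expect_equal(w$weekday_days_used, 30)
  expect_equal(w$weekend_days_used, 12)
  expect_equal(w$days_used, 42)
})

test_that("every emitted window satisfies the eligibility inequality", {
  co <- generate_cohort(cohort_config(n_participants = 40, wear_prob = 0.55,
                                      seed = 19))
  w <- build_windows(co$daily, co$questionnaires)
  expect_true(all(w$days_used >= ceiling(0.5 * 42)))
  expect_true(all(w$days_used <= 42))
  expect_equal(w$weekday_days_used + w$weekend_days_used, w$days_used)
})

test_that("wear summary reproduces the printed percentage arithmetic", {
  # windows engineered to the printed means: 26.9 of 30 weekdays, 10.4 of 12
  # weekend days
  w <- data.frame(participant_id = "p", completion_date = as.Date("2019-01-01"),
                  window_start = as.Date("2018-11-20"),
                  window_end = as.Date("2018-12-31"),
                  days_used = c(rep(38, 5), rep(37, 5)),
                  weekday_days_used = c(rep(27, 9), 26),
                  weekend_days_used = c(rep(10, 6), rep(11, 4)),
                  weekday_capacity = 30, weekend_capacity = 12)
  ws <- wear_summary(w)
  expect_equal(round(ws$weekday_pct, 1), 89.7)  # 26.9 / 30
  expect_equal(round(ws$weekend_pct, 1), 86.7)  # 10.4 / 12
  expect_equal(ws$mean_days_used, 37.5)
  # fully-worn windows give 100% everywhere
  wf <- w
  wf$days_used <- 42; wf$weekday_days_used <- 30; wf$weekend_days_used <- 12
  wsf <- wear_summary(wf)
  expect_equal(wsf$pct_of_window, 100)
  expect_equal(wsf$weekday_pct, 100)
  expect_equal(wsf$weekend_pct, 100)
  expect_error(wear_summary(w[0, ]), "at least one")
})
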