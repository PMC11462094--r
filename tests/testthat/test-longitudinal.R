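make_assignments <- function(q, labels) {
  data.frame(participant_id = q$participant_id,
             completion_date = q$completion_date,
             label = labels, stringsAsFactors = FALSE)
}

test_that("consecutive questionnaires chain into transition records", {
  q <- make_questionnaires(rep("p1", 3),
                           as.Date("2019-01-01") + c(0, 182, 364),
                           scdai = c(200, 150, 100))
  asg <- make_assignments(q, c("low", "moderate", "moderate"))
  rec <- pair_consecutive(q, asg)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$movement_class, c("adjacent_up", "same"))
  expect_equal(rec$score_change, c(-50, -50))
  expect_equal(attr(rec, "n_dropped_gap"), 0L)
})

test_that("pairs outside the gap window are dropped and counted", {
  q <- make_questionnaires(rep("p1", 3),
                           as.Date("2019-01-01") + c(0, 400, 500),
                           scdai = 100)
  asg <- make_assignments(q, rep("low", 3))
  rec <- pair_consecutive(q, asg)
  expect_equal(nrow(rec), 1)            # only the 100-day gap survives
  expect_equal(attr(rec, "n_dropped_gap"), 1L)
  # boundary gaps of exactly 90 and 270 days are kept
  qb <- make_questionnaires(rep("p2", 3),
                            as.Date("2019-01-01") + c(0, 90, 360),
                            scdai = 100)
  recb <- pair_consecutive(qb, make_assignments(qb, rep("low", 3)))
  expect_equal(nrow(recb), 2)
})

test_that("movement classes mirror under direction reversal", {
  labs <- c("low", "moderate", "high")
  mirror <- c(same = "same", adjacent_up = "adjacent_down",
              adjacent_down = "adjacent_up", extreme_up = "extreme_down",
              extreme_down = "extreme_up")
  for (a in labs) for (b in labs) {
    q <- make_questionnaires(rep("p1", 2), as.Date("2019-01-01") + c(0, 182),
                             scdai = 100)
    fwd <- pair_consecutive(q, make_assignments(q, c(a, b)))$movement_class
    rev <- pair_consecutive(q, make_assignments(q, c(b, a)))$movement_class
    expect_equal(rev, unname(mirror[fwd]))
  }
})

test_that("disease-score change uses the index matching the IBD type", {
  q <- make_questionnaires(rep("u1", 2), as.Date("2019-01-01") + c(0, 182),
                           ibd_type = "UC_IC", sccai = c(4, 2))
  rec <- pair_consecutive(q, make_assignments(q, c("moderate", "high")))
  expect_equal(rec$score_change, -2)
  expect_equal(rec$ibd_type, "UC_IC")
})

test_that("paired t matches the closed-form oracle and its conventions", {
  d <- c(-2, -1, 0, 1, -3)
  res <- paired_t_test(d)
  ora <- oracle_paired_t(d)
  expect_equal(res$statistic, ora$t, tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p.value, ora$p, tolerance = 1e-12)
  # all-zero differences
  z <- paired_t_test(rep(0, 6))
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  # constant nonzero differences: degenerate flag, extreme p
  cns <- paired_t_test(rep(2, 6))
  expect_true(cns$degenerate)
  expect_equal(cns$p.value, .Machine$double.xmin)
  expect_equal(cns$statistic, Inf)
})

test_that("paired t is suppressed below the minimum cell size", {
  expect_true(paired_t_test(c(1, 2, 3, 4))$suppressed)     # n = 4 < 5
  expect_false(paired_t_test(c(1, 2, 3, 4, 5))$suppressed)
  expect_true(paired_t_test(1:9, min_n = 10)$suppressed)
})

test_that("transition summary conserves counts and percentages", {
  set.seed(61)
  labs <- c("low", "moderate", "high")
  n <- 120
  rec <- data.frame(participant_id = sprintf("p%03d", 1:n),
                    from_label = sample(labs, n, TRUE),
                    to_label = sample(labs, n, TRUE),
                    ibd_type = sample(c("CD", "UC_IC"), n, TRUE),
                    score_change = rnorm(n), stringsAsFactors = FALSE)
  rec$movement_class <- with(rec, ifelse(from_label == to_label, "same", "move"))
  summ <- summarize_transitions(rec)
  expect_equal(sum(summ$by_category$n), n)
  expect_equal(sum(summ$by_cell$n), n)
  expect_equal(sum(summ$by_category$percent), 100, tolerance = 1e-9)
  # a single record occupies its cell at 100%
  one <- summarize_transitions(rec[1, , drop = FALSE])
  expect_equal(one$total, 1)
  expect_equal(sum(one$by_category$percent == 100), 1)
  expect_error(summarize_transitions(rec[0, ]), "no transition")
})

test_that("identity-chain cohorts never change clusters", {
  cfg <- cohort_config(n_participants = 30, q_mean = 3, q_sd = 0,
                       transition_matrix = diag(3), seed = 67)
  co <- generate_cohort(cfg)
  asg <- data.frame(participant_id = co$truth$participant_id,
                    completion_date = co$truth$completion_date,
                    label = co$truth$phenotype, stringsAsFactors = FALSE)
  rec <- pair_consecutive(co$questionnaires, asg)
  expect_gt(nrow(rec), 0)
  expect_true(all(rec$movement_class == "same"))
})

test_that("planted beneficial-activity effect shows the expected sign pattern", {
  cfg <- cohort_config(n_participants = 400, q_mean = 4, q_sd = 0, seed = 71)
  co <- generate_cohort(cfg)
  asg <- data.frame(participant_id = co$truth$participant_id,
                    completion_date = co$truth$completion_date,
                    label = co$truth$phenotype, stringsAsFactors = FALSE)
  rec <- pair_consecutive(co$questionnaires, asg)
  up <- rec$movement_class %in% c("adjacent_up", "extreme_up")
  down <- rec$movement_class %in% c("adjacent_down", "extreme_down")
  expect_lt(mean(rec$score_change[up & rec$ibd_type == "CD"], na.rm = TRUE), 0)
  expect_gt(mean(rec$score_change[down & rec$ibd_type == "CD"], na.rm = TRUE), 0)
  # with the default chain, the same-cluster share of true transitions sits
  # near 68%
  expect_gt(nrow(rec), 700)
  summ <- summarize_transitions(rec)
  same_pct <- summ$by_category$percent[summ$by_category$category == "same"]
  expect_lt(abs(same_pct - 68), 4)
})
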