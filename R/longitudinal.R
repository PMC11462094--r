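# Longitudinal transition analysis: pair consecutive questionnaires, classify
# movement between activity clusters, test paired disease-score changes with
# small-cell suppression, and summarize transition proportions.

MOVEMENT_CLASSES <- c("same", "adjacent_up", "adjacent_down",
                      "extreme_up", "extreme_down")
PH_RANK <- c(low = 1L, moderate = 2L, high = 3L)

movement_class <- function(from, to) {
  d <- PH_RANK[to] - PH_RANK[from]
  unname(ifelse(d == 0, "same",
    ifelse(d == 1, "adjacent_up",
      ifelse(d == -1, "adjacent_down",
        ifelse(d == 2, "extreme_up", "extreme_down")))))
}

#' Pair consecutive questionnaires into transition records
#'
#' Within each participant, orders cluster-assigned questionnaires by date and
#' turns each adjacent pair whose gap lies in `gap_range` days (default
#' `[90, 270]`, i.e. roughly biannual) into one transition record carrying the
#' from/to cluster labels, the movement class, and the change in the disease
#' index matching the IBD type (SCDAI for CD, SCCAI for UC/IC; never mixed).
#' Pairs outside the gap window are dropped and counted in
#' `attr(x, "n_dropped_gap")`.
#'
#' @param questionnaires Questionnaires ([read_questionnaires()]).
#' @param assignments Data frame with `participant_id`, `completion_date` and
#'   `label` (cluster label per assigned questionnaire window).
#' @param gap_range Allowed gap in days between consecutive questionnaires.
#' @return Data frame of transition records: ids, period dates, `from_label`,
#'   `to_label`, `movement_class`, `ibd_type`, `score_from`, `score_to`,
#'   `score_change`.
#' @export
pair_consecutive <- function(questionnaires, assignments,
                             gap_range = c(90, 270)) {
  stopifnot(all(c("participant_id", "completion_date", "label") %in%
                names(assignments)))
  key_a <- paste(assignments$participant_id, assignments$completion_date)
  key_q <- paste(questionnaires$participant_id, questionnaires$completion_date)
  m <- match(key_a, key_q)
  if (anyNA(m))
    stop("assignment(s) without a matching questionnaire", call. = FALSE)
  q <- questionnaires[m, , drop = FALSE]
  q$label <- as.character(assignments$label)
  q <- q[order(q$participant_id, q$completion_date), , drop = FALSE]

  same_part <- q$participant_id[-nrow(q)] == q$participant_id[-1]
  if (nrow(q) < 2 || !any(same_part)) {
    out <- empty_transitions()
    attr(out, "n_dropped_gap") <- 0L
    return(out)
  }
  i <- which(same_part)                      # index of "from" row; i+1 is "to"
  gap <- as.numeric(q$completion_date[i + 1] - q$completion_date[i])
  keep <- gap >= gap_range[1] & gap <= gap_range[2]
  n_dropped <- sum(!keep)
  i <- i[keep]
  score_col <- ifelse(q$ibd_type[i] == "CD", "scdai", "sccai")
  score_from <- ifelse(score_col == "scdai", q$scdai[i], q$sccai[i])
  score_to <- ifelse(score_col == "scdai", q$scdai[i + 1], q$sccai[i + 1])
  out <- data.frame(participant_id = q$participant_id[i],
                    date_from = q$completion_date[i],
                    date_to = q$completion_date[i + 1],
                    from_label = q$label[i],
                    to_label = q$label[i + 1],
                    movement_class = movement_class(q$label[i], q$label[i + 1]),
                    ibd_type = q$ibd_type[i],
                    score_from = score_from,
                    score_to = score_to,
                    score_change = score_to - score_from,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped_gap") <- n_dropped
  out
}

empty_transitions <- function() {
  data.frame(participant_id = character(0), date_from = as.Date(character(0)),
             date_to = as.Date(character(0)), from_label = character(0),
             to_label = character(0), movement_class = character(0),
             ibd_type = character(0), score_from = numeric(0),
             score_to = numeric(0), score_change = numeric(0),
             stringsAsFactors = FALSE)
}

#' Two-tailed paired t test with small-cell suppression
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided
#' p-value, computed on the paired differences. With fewer than `min_n`
#' differences the test is suppressed (no statistic reported), matching the
#' reporting rule for small transition cells. Zero-variance differences
#' follow explicit conventions: all-zero gives `t = 0, p = 1`; constant
#' nonzero gives a signed infinite t, the smallest representable p, and a
#' degeneracy flag.
#'
#' @param differences Numeric vector of paired differences (finite; missing
#'   values are dropped).
#' @param min_n Minimum number of differences to compute the test.
#' @return List: `n`, `mean`, `sd`, and either `suppressed = TRUE` or
#'   `statistic` (t), `df`, `p.value`, `degenerate`.
#' @export
paired_t_test <- function(differences, min_n = 5) {
  d <- differences[!is.na(differences)]
  if (length(d) && !all(is.finite(d)))
    stop("differences must be finite", call. = FALSE)
  n <- length(d)
  base_out <- list(n = n,
                   mean = if (n) mean(d) else NA_real_,
                   sd = if (n > 1) stats::sd(d) else NA_real_)
  if (n < min_n)
    return(c(base_out, list(suppressed = TRUE)))
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(c(base_out, list(suppressed = FALSE, statistic = 0, df = n - 1,
                              p.value = 1, degenerate = FALSE)))
    return(c(base_out, list(suppressed = FALSE,
                            statistic = sign(mean(d)) * Inf, df = n - 1,
                            p.value = .Machine$double.xmin, degenerate = TRUE)))
  }
  res <- stats::t.test(d)
  c(base_out, list(suppressed = FALSE, statistic = unname(res$statistic),
                   df = unname(res$parameter), p.value = res$p.value,
                   degenerate = FALSE))
}

#' Summarize cluster transitions
#'
#' Counts and percentages of transition records per pooled movement category
#' (same cluster, low<->moderate, moderate<->high, low<->high) and per
#' directed `(from, to)` cell split by IBD type, with the mean (SD) disease
#' score change and a paired t test per cell (suppressed below `min_n`
#' records). Percentages use the pooled record count as denominator and are
#' stored at full precision; printing rounds to one decimal.
#'
#' @param records Transition records from [pair_consecutive()].
#' @param min_n Suppression threshold for the paired t tests.
#' @return Object of class `transition_summary`: `total`, `by_category`
#'   (pooled counts/percents), `by_cell` (per IBD type and directed cell).
#' @export
summarize_transitions <- function(records, min_n = 5) {
  if (is.null(records) || nrow(records) == 0)
    stop("no transition records to summarize", call. = FALSE)
  total <- nrow(records)
  pair_cat <- function(from, to) {
    u <- paste(pmin(PH_RANK[from], PH_RANK[to]), pmax(PH_RANK[from], PH_RANK[to]))
    ifelse(from == to, "same",
      ifelse(u == "1 2", "low_moderate",
        ifelse(u == "2 3", "moderate_high", "low_high")))
  }
  cats <- c("same", "low_moderate", "moderate_high", "low_high")
  cat_counts <- table(factor(pair_cat(records$from_label, records$to_label),
                             levels = cats))
  by_category <- data.frame(category = cats,
                            n = as.integer(cat_counts),
                            percent = 100 * as.integer(cat_counts) / total)

  cells <- expand.grid(ibd_type = c("UC_IC", "CD"),
                       from = PHENOTYPES, to = PHENOTYPES,
                       stringsAsFactors = FALSE)
  cell_rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$ibd_type == cells$ibd_type[i] &
      records$from_label == cells$from[i] & records$to_label == cells$to[i]
    d <- records$score_change[sel]
    tt <- paired_t_test(d, min_n = min_n)
    data.frame(ibd_type = cells$ibd_type[i], from = cells$from[i],
               to = cells$to[i], n = sum(sel),
               mean_change = tt$mean, sd_change = tt$sd,
               t = if (tt$suppressed) NA_real_ else tt$statistic,
               p.value = if (tt$suppressed) NA_real_ else tt$p.value,
               suppressed = tt$suppressed)
  })
  by_cell <- do.call(rbind, cell_rows)
  by_cell <- by_cell[order(by_cell$ibd_type, PH_RANK[by_cell$from],
                           PH_RANK[by_cell$to]), , drop = FALSE]
  rownames(by_cell) <- NULL
  structure(list(total = total, by_category = by_category, by_cell = by_cell,
                 min_n = min_n),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("Cluster transitions: %d consecutive questionnaire pairs\n", x$total))
  bc <- x$by_category
  bc$percent <- round(bc$percent, 1)
  print(bc, row.names = FALSE)
  cat(sprintf("\nPer-cell disease-score change (paired t suppressed for n < %d)\n",
              x$min_n))
  tab <- x$by_cell[x$by_cell$n > 0, , drop = FALSE]
  tab$mean_change <- round(tab$mean_change, 1)
  tab$sd_change <- round(tab$sd_change, 1)
  tab$t <- round(tab$t, 2)
  tab$p.value <- signif(tab$p.value, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
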