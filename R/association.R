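# Cross-sectional comparison of patient-reported outcomes and participant
# characteristics across activity clusters: per-cluster means/SDs with one-way
# ANOVA for continuous variables, counts/percentages with chi-square tests for
# categorical ones. The unit of analysis is the activity window (period), as
# in the emulated study; repeated windows per participant are not adjusted
# for, which is a documented caveat.

#' One-way analysis of variance across groups
#'
#' F statistic from between/within mean squares with an upper-tail F p-value.
#' Degenerate inputs follow explicit conventions: all observations identical
#' everywhere gives `F = 0, p = 1`; zero within-group variance with unequal
#' group means gives an infinite F, the smallest representable p, and a
#' degeneracy flag.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 finite
#'   observations), or a single numeric vector with `g` giving group labels.
#' @param g Optional grouping vector when `groups` is a single vector.
#' @return List: `statistic` (F), `df1`, `df2`, `p.value`, `degenerate`.
#' @export
oneway_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  y <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df1 <- nlevels(f) - 1L
  df2 <- length(y) - nlevels(f)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  means <- vapply(groups, mean, numeric(1))
  if (ssw == 0) {
    if (max(means) - min(means) == 0)
      return(list(statistic = 0, df1 = df1, df2 = df2, p.value = 1,
                  degenerate = FALSE))
    return(list(statistic = Inf, df1 = df1, df2 = df2,
                p.value = .Machine$double.xmin, degenerate = TRUE))
  }
  res <- stats::oneway.test(y ~ f, var.equal = TRUE)
  list(statistic = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p.value = res$p.value,
       degenerate = FALSE)
}

#' Pearson chi-square test of independence
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the margins and
#' `df = (r - 1)(c - 1)`. A warning is raised (and a flag set) when any
#' expected count is below 5; a zero row or column margin is an error.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return List: `statistic`, `df`, `p.value`, `expected`, `low_expected`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || nrow(tab) < 2 || ncol(tab) < 2)
    stop("need a matrix of non-negative counts, at least 2x2", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(res$expected < 5)
  if (low)
    warning("chi-square approximation: expected count below 5", call. = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p.value = res$p.value, expected = res$expected, low_expected = low)
}

#' Profile activity clusters against outcomes and characteristics
#'
#' Builds the cross-sectional cluster profile: for each continuous variable,
#' per-cluster mean, SD and n plus a one-way ANOVA across clusters; for each
#' categorical variable, per-cluster counts and percentages plus a chi-square
#' test. Disease indices are profiled within the matching IBD subtype only
#' (SCDAI among Crohn disease windows, SCCAI among UC/IC windows). Missing
#' values are excluded variable-by-variable, with the n retained reported.
#'
#' @param windows Activity windows ([build_windows()]).
#' @param assignments Cluster label per window, parallel to `windows` (e.g.
#'   the `cluster_label` of a labeled [activity_kmeans()] fit).
#' @param questionnaires Questionnaires to link by
#'   `(participant_id, completion_date)`.
#' @param continuous,categorical Variable names to profile; defaults cover
#'   the activity features, PRO scores and main covariates present.
#' @return Object of class `cluster_profile`: `n` per cluster, `continuous`
#'   (one row per variable x cluster plus test columns), `categorical`
#'   (list of count tables with tests).
#' @export
profile_clusters <- function(windows, assignments, questionnaires,
                             continuous = NULL, categorical = NULL) {
  stopifnot(nrow(windows) == length(assignments))
  key_w <- paste(windows$participant_id, windows$completion_date)
  key_q <- paste(questionnaires$participant_id, questionnaires$completion_date)
  m <- match(key_w, key_q)
  if (anyNA(m))
    stop("every window must link to a questionnaire", call. = FALSE)
  q <- questionnaires[m, , drop = FALSE]
  dat <- cbind(windows, q[, setdiff(names(q), names(windows)), drop = FALSE])
  dat$.cluster <- factor(assignments)

  if (is.null(continuous))
    continuous <- intersect(c("mean_steps", "mean_distance_miles",
                              "mean_mvpa_minutes", "mean_calories",
                              PROMIS_DOMAINS, "scdai", "sccai",
                              "age", "bmi", "disease_duration_years"),
                            names(dat))
  if (is.null(categorical))
    categorical <- intersect(c("gender", "smoking", "education",
                               "current_5asa", "current_biologic",
                               "current_corticosteroid",
                               "current_immunomodulator"),
                             names(dat))
  missing_vars <- setdiff(c(continuous, categorical), names(dat))
  if (length(missing_vars))
    stop("variable(s) absent from data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)

  lev <- levels(dat$.cluster)
  cont_rows <- lapply(continuous, function(v) {
    d <- dat
    if (v == "scdai") d <- d[d$ibd_type == "CD", , drop = FALSE]
    if (v == "sccai") d <- d[d$ibd_type == "UC_IC", , drop = FALSE]
    ok <- !is.na(d[[v]])
    groups <- split(d[[v]][ok], d$.cluster[ok], drop = FALSE)
    test <- tryCatch(oneway_anova(groups),
                     error = function(e) list(statistic = NA_real_,
                                              df1 = NA, df2 = NA,
                                              p.value = NA_real_,
                                              degenerate = NA))
    stats_tab <- do.call(rbind, lapply(lev, function(cl) {
      vv <- groups[[cl]]
      data.frame(variable = v, cluster = cl, n = length(vv),
                 mean = if (length(vv)) mean(vv) else NA_real_,
                 sd = if (length(vv) > 1) stats::sd(vv) else NA_real_)
    }))
    stats_tab$F <- test$statistic
    stats_tab$p.value <- test$p.value
    stats_tab
  })
  cont <- do.call(rbind, cont_rows)

  cat_list <- lapply(categorical, function(v) {
    ok <- !is.na(dat[[v]])
    tab <- table(dat[[v]][ok], dat$.cluster[ok])
    test <- tryCatch(suppressWarnings(chi_square_independence(tab)),
                     error = function(e) list(statistic = NA_real_, df = NA,
                                              p.value = NA_real_,
                                              low_expected = NA))
    list(variable = v, counts = tab,
         percent = prop.table(tab, margin = 2) * 100,
         statistic = test$statistic, df = test$df, p.value = test$p.value,
         low_expected = test$low_expected)
  })
  names(cat_list) <- categorical

  structure(list(n = table(dat$.cluster),
                 continuous = cont, categorical = cat_list),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, digits = 1, ...) {
  cat("Cluster profile (unit of analysis: activity window)\n")
  cat("  windows per cluster:",
      paste(sprintf("%s %d", names(x$n), x$n), collapse = ", "), "\n\n")
  tab <- x$continuous
  tab$mean <- round(tab$mean, digits)
  tab$sd <- round(tab$sd, digits)
  tab$F <- round(tab$F, 2)
  tab$p.value <- signif(tab$p.value, 2)
  print(tab, row.names = FALSE)
  for (v in names(x$categorical)) {
    ct <- x$categorical[[v]]
    cat(sprintf("\n%s (chi-square %.2f, df %s, p %s%s)\n", v,
                ct$statistic, format(ct$df), format(signif(ct$p.value, 2)),
                if (isTRUE(ct$low_expected)) "; expected count < 5" else ""))
    print(ct$counts)
  }
  invisible(x)
}
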