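# Independent oracles: deliberately naive implementations (loops, direct
# formulas, exhaustive enumeration) used to verify the package's vectorized
# implementations. They share no code with R/.

# silhouette by the displayed formula, double loop
oracle_silhouette <- function(x, cl) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (c2 in setdiff(unique(cl), cl[i])) {
      others <- which(cl == c2)
      b <- min(b, mean(vapply(others, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# global-optimum SSE over all 2-partitions (both clusters non-empty)
oracle_best_sse_k2 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point n in cluster 0 to halve work
    in1 <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sse <- 0
    for (g in list(which(in1), which(!in1))) {
      cen <- colMeans(x[g, , drop = FALSE])
      sse <- sse + sum(sweep(x[g, , drop = FALSE], 2, cen)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# adjusted Rand index by explicit pair concordance counts
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# Spearman rho via hand-computed average ranks + product-moment formula
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# one-way ANOVA from explicit sums of squares
oracle_anova <- function(groups) {
  y <- unlist(groups)
  grand <- mean(y)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Pearson chi-square from margins, cell by cell
oracle_chisq <- function(tab) {
  n <- sum(tab)
  x2 <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    x2 <- x2 + (tab[i, j] - e)^2 / e
  }
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(X2 = x2, df = df, p = stats::pchisq(x2, df, lower.tail = FALSE))
}

# type-7 quantile (linear interpolation) and Tukey fences, by hand
oracle_tukey_fences <- function(v) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  q7 <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, n)] - v[lo])
  }
  q1 <- q7(0.25); q3 <- q7(0.75)
  c(lower = q1 - 1.5 * (q3 - q1), upper = q3 + 1.5 * (q3 - q1))
}

# paired t statistic from the closed-form definition
oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
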