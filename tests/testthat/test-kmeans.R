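test_that("k-means++ seeding obeys its boundary cases", {
  set.seed(1)
  x <- matrix(rnorm(16), 8, 2)
  # k = n: every point eventually has squared distance 0, so the seeds are a
  # permutation of the points
  cent <- kmeanspp_init(x, 8)
  expect_equal(dim(cent), c(8, 2))
  expect_equal(cent[order(cent[, 1]), ], x[order(x[, 1]), ], ignore_attr = TRUE)
  # k = 1: a single point
  one <- kmeanspp_init(x, 1)
  expect_true(any(apply(x, 1, function(r) all(r == one[1, ]))))
  expect_error(kmeanspp_init(x, 9), "k must be")
})

test_that("k-means++ D^2 law rarely seeds both centroids in one pair", {
  pairs <- rbind(c(0, 0), c(0, 0.1), c(100, 0), c(100, 0.1))
  set.seed(99)
  same <- 0L
  for (i in 1:1000) {
    cent <- kmeanspp_init(pairs, 2)
    if (abs(cent[1, 1] - cent[2, 1]) < 1) same <- same + 1L
  }
  expect_lt(same / 1000, 0.05)
})

test_that("Lloyd closed-form cases: k = 1 and k = n", {
  set.seed(2)
  x <- matrix(rnorm(20), 10, 2)
  f1 <- activity_kmeans(x, k = 1, n_init = 1, seed = 1,
                        compute_silhouette = FALSE)
  expect_equal(as.numeric(f1$centroids), colMeans(x), tolerance = 1e-10)
  expect_equal(f1$sse, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-10)
  fn <- activity_kmeans(x, k = 10, n_init = 5, seed = 1,
                        compute_silhouette = FALSE)
  expect_equal(fn$sse, 0, tolerance = 1e-12)
})

test_that("SSE is non-increasing within a run and across n_init", {
  set.seed(3)
  for (i in 1:5) {
    x <- matrix(rnorm(60 * 2), 60, 2)
    fit <- activity_kmeans(x, k = 3, n_init = 1, seed = i)
    expect_true(all(diff(fit$sse_trace) <= 1e-9))
    multi <- activity_kmeans(x, k = 3, n_init = 20, seed = i)
    expect_lte(multi$sse, fit$sse + 1e-9)
  }
})

test_that("each point ends at its nearest centroid and SSE is consistent", {
  set.seed(4)
  x <- matrix(rnorm(80), 40, 2)
  fit <- activity_kmeans(x, k = 4, seed = 7)
  d2 <- outer(rowSums(x^2), rowSums(fit$centroids^2), "+") -
    2 * x %*% t(fit$centroids)
  expect_equal(fit$cluster, apply(d2, 1, which.min))
  expect_equal(fit$sse, sum(d2[cbind(1:40, fit$cluster)]), tolerance = 1e-8)
})

test_that("a fixed seed gives a bit-identical model", {
  x <- make_blob_windows(n_per = 30, seed = 5)[, 1:3]
  f1 <- activity_kmeans(x, k = 3, seed = 42)
  f2 <- activity_kmeans(x, k = 3, seed = 42)
  f1$call <- f2$call <- NULL
  expect_identical(f1, f2)
})

test_that("non-finite input is rejected", {
  x <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(activity_kmeans(x, k = 1), "finite")
})

test_that("silhouette matches the hand-evaluated 1-D example", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  sil <- silhouette_coefficients(x, c(1, 1, 2, 2))
  # point 0: a = 0.1, b = (10 + 10.1)/2 = 10.05, s = (10.05 - 0.1)/10.05
  expect_equal(sil$widths$s[1], (10.05 - 0.1) / 10.05, tolerance = 1e-12)
  expect_equal(round(sil$widths$s[1], 4), 0.99)
})

test_that("silhouette singleton convention and error branch", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  sil <- silhouette_coefficients(x, c(1, 1, 2))
  expect_equal(sil$widths$s[3], 0)        # singleton cluster -> s = 0
  expect_error(silhouette_coefficients(x, c(1, 1, 1)), "single cluster")
})

test_that("silhouette agrees with the direct-formula oracle to 1e-12", {
  set.seed(6)
  for (i in 1:5) {
    x <- matrix(rnorm(24), 12, 2)
    cl <- sample(1:3, 12, replace = TRUE)
    if (length(unique(cl)) < 2) next
    sil <- silhouette_coefficients(x, cl)
    expect_equal(sil$widths$s, oracle_silhouette(x, cl), tolerance = 1e-12)
    expect_equal(sil$average, mean(oracle_silhouette(x, cl)), tolerance = 1e-12)
  }
})

test_that("the SSE elbow scan terminates at zero and drops hardest at k = 3", {
  x <- make_blob_windows(n_per = 25, seed = 7)[, 1:3]
  scan <- sse_scan(x[1:10, ], k_range = c(1, 5, 10), n_init = 10, seed = 1)
  expect_lt(scan$sse[3] / scan$sse[1], 1e-12)  # k = n ends the curve at ~0
  full <- sse_scan(x, k_range = 1:5, n_init = 10, seed = 1)
  expect_true(all(diff(full$sse) < 0))
  rel_drop <- -diff(full$sse) / full$sse[-nrow(full)]
  expect_equal(which.max(rel_drop) + 1L, 3L)  # largest relative drop at k = 3
})

test_that("silhouette-based K selection recovers planted structure", {
  x3 <- make_blob_windows(n_per = 40, seed = 8)[, 1:3]
  expect_equal(select_k(x3, 2, 5, seed = 1)$k, 3)
  # two planted blobs
  set.seed(9)
  x2 <- data.frame(a = c(rnorm(40, 0), rnorm(40, 50)), b = rnorm(80))
  expect_equal(select_k(x2, 2, 5, seed = 1)$k, 2)
  # degenerate range returns that k
  expect_equal(select_k(x3, 4, 4, seed = 1)$k, 4)
})

test_that("feature-subset search counts subsets and excludes noise features", {
  w <- make_blob_windows(n_per = 40, seed = 10)
  w$weekday_days_used <- runif(nrow(w), 25, 30)
  w$weekend_days_used <- runif(nrow(w), 9, 12)
  fs <- feature_subset_search(w, k = 3, n_init = 5, seed = 1)
  expect_equal(fs$n_subsets, 2^6 - 6 - 1)   # 57 subsets of size >= 2
  # independent-noise calories feature is excluded by the winner in a
  # majority of seeds
  wins <- vapply(1:5, function(s) {
    w2 <- make_blob_windows(n_per = 40, seed = s)
    fs2 <- feature_subset_search(
      w2, candidate_features = c("mean_steps", "mean_distance_miles",
                                 "mean_mvpa_minutes", "mean_calories"),
      k = 3, n_init = 5, seed = s)
    !"mean_calories" %in% fs2$best_features
  }, logical(1))
  expect_gte(sum(wins), 3)
  # single candidate subset is returned trivially
  one <- feature_subset_search(w, candidate_features = c("mean_steps",
                                                         "mean_distance_miles"),
                               k = 3, n_init = 5, seed = 1)
  expect_equal(one$n_subsets, 1)
  expect_equal(sort(one$best_features), c("mean_distance_miles", "mean_steps"))
  expect_error(feature_subset_search(w, candidate_features = character(0)),
               "empty")
  expect_error(feature_subset_search(w, candidate_features = "nope"),
               "not found")
})

test_that("clusters are labeled low/moderate/high by ascending centroid steps", {
  w <- make_blob_windows(n_per = 30, seed = 11)[, 1:3]
  fit <- label_clusters(activity_kmeans(w, k = 3, seed = 1))
  cent <- coef(fit)
  expect_equal(rownames(cent)[order(cent[, "mean_steps"])],
               c("low", "moderate", "high"))
  # labeling is independent of centroid storage order: relabel a permuted fit
  perm <- fit
  p <- c(3, 1, 2)
  perm$centroids <- fit$centroids[p, ]
  perm$cluster <- match(fit$cluster, p)
  perm <- label_clusters(perm)
  expect_equal(as.character(perm$cluster_label), as.character(fit$cluster_label))
  # k != 3 falls back to ordinal labels
  f2 <- label_clusters(activity_kmeans(w, k = 2, seed = 1))
  expect_equal(sort(f2$labels), c("level_1", "level_2"))
})

test_that("model methods are mutually consistent", {
  w <- make_blob_windows(n_per = 25, seed = 12)[, 1:3]
  fit <- label_clusters(activity_kmeans(w, k = 3, seed = 3))
  expect_equal(as.character(predict(fit, w)), as.character(fit$cluster_label))
  expect_equal(fitted(fit), coef(fit)[fit$cluster, ], ignore_attr = TRUE)
  res <- residuals(fit, w)
  expect_equal(as.matrix(w) + 0, fitted(fit) + res, ignore_attr = TRUE)
  expect_output(print(fit), "k = 3")
  expect_output(print(summary(fit)), "Cluster profile")
})

test_that("scaled fits reproduce raw-scale centroids through coef", {
  w <- make_blob_windows(n_per = 25, seed = 13)[, 1:3]
  fit <- label_clusters(activity_kmeans(w, k = 3, seed = 3, scale = "zscore"))
  cent <- coef(fit)
  expect_equal(unname(sort(cent[, "mean_steps"])),
               as.numeric(sort(tapply(w$mean_steps, fit$cluster, mean))),
               tolerance = 500)
})
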