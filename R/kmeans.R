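# The clustering core: k-means++ seeding, Lloyd iterations minimizing the
# sum of squared errors (SSE, cluster scatter), silhouette validation, SSE
# elbow scan, silhouette-driven K and feature-subset selection, and ordered
# low/moderate/high labeling. Implemented from first principles: this is the
# methodological core of the pipeline, so the algorithm is authored here
# rather than delegated.

# squared Euclidean distances, n x k
dist2_to_centroids <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") - 2 * x %*% t(centroids)
  pmax(d2, 0)  # guard tiny negatives from cancellation
}

#' k-means++ centroid seeding
#'
#' The first centroid is drawn uniformly from the points; each subsequent
#' centroid is drawn with probability proportional to the squared distance to
#' the nearest centroid already chosen, placing seeds generally far apart.
#' Uses the current RNG stream.
#'
#' @param x Numeric matrix of points (rows).
#' @param k Number of centroids, `1 <= k <= nrow(x)`.
#' @return A `k x ncol(x)` matrix of centroids (rows of `x`).
#' @export
kmeanspp_init <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1 || k > n) stop("k must be in [1, number of points]", call. = FALSE)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      tot <- sum(d2)
      idx[j] <- if (tot <= 0) {
        remaining <- setdiff(seq_len(n), idx[seq_len(j - 1)])
        if (length(remaining)) remaining[sample.int(length(remaining), 1)]
        else sample.int(n, 1)
      } else {
        sample.int(n, 1, prob = d2 / tot)
      }
      d2j <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, d2j)
    }
  }
  out <- x[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One Lloyd run from given initial centroids. Assignment ties break to the
# lowest cluster index; an empty cluster is reseeded at the point farthest
# from its own centroid (which can only decrease the SSE). Convergence when
# the Frobenius norm of the centroid displacement drops below tol.
lloyd_run <- function(x, centroids, max_iter, tol) {
  n <- nrow(x); k <- nrow(centroids)
  sse_trace <- numeric(0)
  assign_pts <- function(cent) {
    d2 <- dist2_to_centroids(x, cent)
    cl <- max.col(-d2, ties.method = "first")
    list(cl = cl, sse = sum(d2[cbind(seq_len(n), cl)]))
  }
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    a <- assign_pts(centroids)
    empty <- setdiff(seq_len(k), unique(a$cl))
    if (length(empty)) {
      d2 <- dist2_to_centroids(x, centroids)
      dist_own <- d2[cbind(seq_len(n), a$cl)]
      for (j in empty) {
        far <- which.max(dist_own)
        centroids[j, ] <- x[far, ]
        dist_own[far] <- -Inf
      }
      a <- assign_pts(centroids)
    }
    sse_trace <- c(sse_trace, a$sse)
    counts <- tabulate(a$cl, nbins = k)
    new_cent <- rowsum(x, a$cl, reorder = FALSE)
    ord <- as.integer(rownames(new_cent))
    upd <- centroids
    upd[ord, ] <- new_cent / counts[ord]
    shift <- sqrt(sum((upd - centroids)^2))
    centroids <- upd
    if (shift < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  final <- assign_pts(centroids)
  list(centroids = centroids, cluster = final$cl, sse = final$sse,
       iterations = iter, converged = converged, sse_trace = sse_trace)
}

#' Fit activity clusters by k-means (Lloyd's method)
#'
#' The package's central fit. Runs Lloyd's algorithm `n_init` times from
#' k-means++ (or uniformly random) seeds and keeps the run with the lowest
#' SSE. Iterations alternate nearest-centroid assignment (Euclidean distance,
#' ties to the lowest cluster index) and centroid mean updates, stopping when
#' the Frobenius norm of the centroid displacement falls below `tol` or after
#' `max_iter` iterations; an empty cluster is reseeded at the point farthest
#' from its centroid. Features are clustered on their raw scale by default
#' (feature scaling is available but has little effect on these data);
#' silhouette coefficients are computed when `k >= 2`.
#'
#' @param x Numeric matrix or data frame of feature columns (one row per
#'   activity window).
#' @param k Number of clusters.
#' @param init Seeding method: `"kmeanspp"` (default) or `"random"`.
#' @param n_init Number of independent initializations.
#' @param max_iter Maximum Lloyd iterations per run.
#' @param tol Convergence tolerance on the centroid displacement norm.
#' @param seed Integer seed for reproducible seeding, or `NULL` for
#'   nondeterministic initialization from the current RNG.
#' @param scale Optional feature scaling: `"none"`, `"zscore"`, `"minmax"`.
#' @param compute_silhouette Compute silhouette coefficients (O(n^2)).
#' @return An object of class `activity_kmeans`: `centroids` (k x d),
#'   `cluster` (assignments), `sse`, `silhouette` (see
#'   [silhouette_coefficients()]), `iterations`, `converged`, `sse_trace`,
#'   plus the fit parameters. Methods: `print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @seealso [label_clusters()], [select_k()], [feature_subset_search()]
#' @export
activity_kmeans <- function(x, k = 3, init = c("kmeanspp", "random"),
                            n_init = 10, max_iter = 300, tol = 1e-4,
                            seed = NULL, scale = c("none", "zscore", "minmax"),
                            compute_silhouette = TRUE) {
  init <- match.arg(init)
  scale <- match.arg(scale)
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  if (!all(is.finite(xm))) stop("points must be finite", call. = FALSE)
  n <- nrow(xm)
  if (k < 1 || n < k) stop("need n >= k >= 1", call. = FALSE)
  stopifnot(n_init >= 1, max_iter >= 1, tol >= 0)

  sc <- switch(scale,
    none = list(center = rep(0, ncol(xm)), scale = rep(1, ncol(xm))),
    zscore = list(center = colMeans(xm), scale = apply(xm, 2, stats::sd)),
    minmax = list(center = apply(xm, 2, min),
                  scale = apply(xm, 2, max) - apply(xm, 2, min)))
  sc$scale[sc$scale == 0] <- 1
  xs <- sweep(sweep(xm, 2, sc$center), 2, sc$scale, "/")

  fit <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      cent0 <- if (init == "kmeanspp") kmeanspp_init(xs, k)
               else xs[sample.int(n, k), , drop = FALSE]
      run <- lloyd_run(xs, cent0, max_iter, tol)
      if (is.null(best) || run$sse < best$sse) best <- run
    }
    best
  })
  colnames(fit$centroids) <- colnames(xm)
  sil <- if (compute_silhouette && k >= 2 && length(unique(fit$cluster)) >= 2)
    silhouette_coefficients(xs, fit$cluster) else NULL
  structure(list(centroids = fit$centroids, cluster = fit$cluster,
                 sse = fit$sse, silhouette = sil,
                 iterations = fit$iterations, converged = fit$converged,
                 sse_trace = fit$sse_trace,
                 feature_names = colnames(xm), k = as.integer(k),
                 n = n, scale = scale, scaling = sc,
                 params = list(init = init, n_init = n_init,
                               max_iter = max_iter, tol = tol, seed = seed),
                 labels = NULL, cluster_label = NULL,
                 call = match.call()),
            class = "activity_kmeans")
}

#' Silhouette coefficients for a clustering
#'
#' For each point x, `a_x` is the mean distance to the other points of its own
#' cluster, `b_x` the smallest mean distance to the points of any other
#' cluster, and `s_x = (b_x - a_x) / max(a_x, b_x)`; a point alone in its
#' cluster has `s_x = 0` by convention. Higher values indicate more cohesive,
#' better-separated clusters.
#'
#' @param x Numeric matrix of points.
#' @param cluster Integer cluster assignments (at least 2 non-empty clusters).
#' @return List with `widths` (data frame: cluster, `a`, `b`, `s` per point),
#'   `cluster_means` (mean `s` per cluster) and `average` (overall mean `s`).
#' @export
silhouette_coefficients <- function(x, cluster) {
  x <- as.matrix(x)
  cluster <- as.integer(cluster)
  stopifnot(nrow(x) == length(cluster))
  sizes <- table(cluster)
  if (length(sizes) < 2)
    stop("silhouette undefined for a single cluster", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  n <- nrow(x)
  # sum of distances from each point to every cluster: k x n
  ks <- sort(unique(cluster))
  sums <- rowsum(D, factor(cluster, levels = ks))
  counts <- as.numeric(sizes[as.character(ks)])
  own <- match(cluster, ks)
  a <- numeric(n); b <- numeric(n)
  for (i in seq_len(n)) {
    ni <- counts[own[i]]
    a[i] <- if (ni > 1) sums[own[i], i] / (ni - 1) else NA_real_
    b[i] <- min(sums[-own[i], i] / counts[-own[i]])
  }
  s <- ifelse(is.na(a), 0, (b - a) / pmax(a, b))
  widths <- data.frame(cluster = cluster, a = a, b = b, s = s)
  cl_means <- tapply(s, cluster, mean)
  list(widths = widths,
       cluster_means = cl_means,
       average = mean(s))
}

#' SSE elbow scan over cluster counts
#'
#' Best-of-`n_init` SSE for each candidate K, for elbow inspection (the K at
#' which the SSE decrease plateaus). Emits the table; the elbow itself is
#' chosen by inspection, complemented by the silhouette scan of [select_k()].
#'
#' @param x Feature matrix.
#' @param k_range Candidate cluster counts.
#' @param ... Passed to [activity_kmeans()] (e.g. `n_init`, `seed`).
#' @return Data frame of class `sse_scan` with columns `k`, `sse`.
#' @export
sse_scan <- function(x, k_range = 1:8, ...) {
  stopifnot(all(k_range >= 1), all(k_range <= nrow(as.matrix(x))))
  sse <- vapply(k_range, function(k)
    activity_kmeans(x, k = k, compute_silhouette = FALSE, ...)$sse, numeric(1))
  structure(data.frame(k = k_range, sse = sse), class = c("sse_scan", "data.frame"))
}

#' @export
plot.sse_scan <- function(x, ...) {
  graphics::plot(x$k, x$sse, type = "b", pch = 19,
                 xlab = "number of clusters K", ylab = "SSE (cluster scatter)",
                 main = "SSE elbow plot", ...)
  invisible(x)
}

#' Select the number of clusters by average silhouette
#'
#' Fits each K in `[k_min, k_max]` and returns the K with the highest average
#' silhouette coefficient (ties go to the smaller K).
#'
#' @param x Feature matrix.
#' @param k_min,k_max Range of K to evaluate.
#' @param ... Passed to [activity_kmeans()].
#' @return List with `k` (selected), `diagnostics` (per-K average silhouette
#'   and SSE) and `fit` (the selected model).
#' @export
select_k <- function(x, k_min = 2, k_max = 5, ...) {
  stopifnot(k_min >= 2, k_max >= k_min, nrow(as.matrix(x)) > k_max)
  ks <- k_min:k_max
  fits <- lapply(ks, function(k) activity_kmeans(x, k = k, ...))
  avg <- vapply(fits, function(f) f$silhouette$average, numeric(1))
  best <- which(avg == max(avg))[1]  # ties: smaller k
  list(k = ks[best],
       diagnostics = data.frame(k = ks, avg_silhouette = avg,
                                sse = vapply(fits, `[[`, numeric(1), "sse")),
       fit = fits[[best]])
}

#' Exhaustive feature-subset search by average silhouette
#'
#' Evaluates every subset (size >= 2) of the candidate features by clustering
#' on the raw (unscaled) feature values and scoring the average silhouette
#' coefficient; returns the winning subset with the full ranking. With 6
#' candidates this evaluates 2^6 - 6 - 1 = 57 subsets.
#'
#' @param windows Activity windows ([build_windows()]), or any data frame
#'   containing the candidate feature columns.
#' @param candidate_features Column names to search over; defaults to the
#'   window-mean activity features plus wear-day counts.
#' @param k Number of clusters per evaluation.
#' @param ... Passed to [activity_kmeans()] (e.g. `n_init`, `seed`).
#' @return Object of class `feature_search`: `ranking` (one row per subset,
#'   sorted by decreasing silhouette), `best_features`, `best_model`.
#' @export
feature_subset_search <- function(windows,
                                  candidate_features = c(
                                    "mean_steps", "mean_distance_miles",
                                    "mean_mvpa_minutes", "mean_calories",
                                    "weekday_days_used", "weekend_days_used"),
                                  k = 3, ...) {
  if (length(candidate_features) == 0)
    stop("candidate feature set is empty", call. = FALSE)
  missing_cols <- setdiff(candidate_features, names(windows))
  if (length(missing_cols))
    stop("feature column(s) not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m <- length(candidate_features)
  subsets <- unlist(lapply(2:max(2, m), function(sz)
    if (sz <= m) utils::combn(candidate_features, sz, simplify = FALSE)),
    recursive = FALSE)
  if (m < 2) subsets <- list(candidate_features)
  rows <- vector("list", length(subsets))
  best_model <- NULL; best_sil <- -Inf; best_features <- NULL
  for (i in seq_along(subsets)) {
    feats <- subsets[[i]]
    fit <- activity_kmeans(windows[, feats, drop = FALSE], k = k, ...)
    sil <- fit$silhouette$average
    rows[[i]] <- data.frame(features = paste(feats, collapse = "+"),
                            n_features = length(feats),
                            avg_silhouette = sil, sse = fit$sse)
    if (sil > best_sil) {
      best_sil <- sil; best_model <- fit; best_features <- feats
    }
  }
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$avg_silhouette), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking, best_features = best_features,
                 best_model = best_model, n_subsets = length(subsets)),
            class = "feature_search")
}

#' @export
print.feature_search <- function(x, ...) {
  cat(sprintf("Feature-subset search: %d subsets evaluated\n", x$n_subsets))
  cat("best subset:", paste(x$best_features, collapse = " + "), "\n")
  cat(sprintf("average silhouette: %.3f\n", x$ranking$avg_silhouette[1]))
  print(utils::head(x$ranking, 5), row.names = FALSE)
  invisible(x)
}

#' Order and label clusters by activity level
#'
#' Assigns interpretable labels by ascending centroid steps: with `k = 3`,
#' `low` < `moderate` < `high` physical activity; for other K, ordinal labels
#' `level_1 .. level_k`. The steps feature is located by name (any feature
#' name containing "steps"), falling back to the first feature.
#'
#' @param model A fitted [activity_kmeans()] model.
#' @return The model with `labels` (per cluster index) and `cluster_label`
#'   (per point, an ordered factor) filled in.
#' @export
label_clusters <- function(model) {
  stopifnot(inherits(model, "activity_kmeans"))
  steps_col <- grep("steps", model$feature_names, value = TRUE)
  key <- if (length(steps_col)) model$centroids[, steps_col[1]]
         else model$centroids[, 1]
  ord <- order(key)  # ascending centroid steps
  lab <- if (model$k == 3) PHENOTYPES else paste0("level_", seq_len(model$k))
  labels <- character(model$k)
  labels[ord] <- lab
  model$labels <- labels
  model$cluster_label <- factor(labels[model$cluster], levels = lab, ordered = TRUE)
  model
}

#' @export
print.activity_kmeans <- function(x, digits = 4, ...) {
  cat(sprintf("Activity k-means fit: k = %d, n = %d, features: %s\n",
              x$k, x$n, paste(x$feature_names, collapse = ", ")))
  sizes <- tabulate(x$cluster, x$k)
  nm <- x$labels %||% paste0("cluster_", seq_len(x$k))
  cat("  sizes:", paste(sprintf("%s %d (%.1f%%)", nm, sizes, 100 * sizes / x$n),
                        collapse = ", "), "\n")
  cat(sprintf("  SSE: %s  iterations: %d (%s)\n", format(x$sse, digits = digits),
              x$iterations, if (x$converged) "converged" else "max_iter reached"))
  if (!is.null(x$silhouette))
    cat(sprintf("  average silhouette: %.3f\n", x$silhouette$average))
  invisible(x)
}

#' @export
summary.activity_kmeans <- function(object, ...) {
  sizes <- tabulate(object$cluster, object$k)
  tab <- data.frame(cluster = seq_len(object$k),
                    label = object$labels %||% rep(NA_character_, object$k),
                    n = sizes, pct = round(100 * sizes / object$n, 1))
  if (!is.null(object$silhouette))
    tab$silhouette <- round(as.numeric(
      object$silhouette$cluster_means[as.character(seq_len(object$k))]), 3)
  tab <- cbind(tab, round(object$centroids, 1))
  structure(list(table = tab, sse = object$sse,
                 average_silhouette = object$silhouette$average %||% NA_real_),
            class = "summary.activity_kmeans")
}

#' @export
print.summary.activity_kmeans <- function(x, ...) {
  cat("Cluster profile\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("SSE: %s   average silhouette: %.3f\n",
              format(x$sse, digits = 4), x$average_silhouette))
  invisible(x)
}

#' @export
coef.activity_kmeans <- function(object, ...) {
  cent <- sweep(sweep(object$centroids, 2, object$scaling$scale, "*"),
                2, object$scaling$center, "+")
  if (!is.null(object$labels)) rownames(cent) <- object$labels
  cent
}

#' Assign new activity windows to fitted clusters
#'
#' @param object Fitted [activity_kmeans()] model.
#' @param newdata Matrix or data frame with the model's feature columns.
#' @param ... Unused.
#' @return Cluster labels (if the model is labeled) or integer indices.
#' @export
predict.activity_kmeans <- function(object, newdata, ...) {
  xm <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(xm) <- "double"
  xs <- sweep(sweep(xm, 2, object$scaling$center), 2, object$scaling$scale, "/")
  cl <- max.col(-dist2_to_centroids(xs, object$centroids), ties.method = "first")
  if (!is.null(object$labels))
    factor(object$labels[cl], levels = sort_levels(object$labels))
  else cl
}

sort_levels <- function(labels) {
  if (all(labels %in% PHENOTYPES)) PHENOTYPES[PHENOTYPES %in% labels]
  else sort(labels)
}

#' @export
fitted.activity_kmeans <- function(object, ...) {
  coef_raw <- sweep(sweep(object$centroids, 2, object$scaling$scale, "*"),
                    2, object$scaling$center, "+")
  coef_raw[object$cluster, , drop = FALSE]
}

#' @export
residuals.activity_kmeans <- function(object, x, ...) {
  if (missing(x)) stop("supply the original feature matrix `x`", call. = FALSE)
  as.matrix(x[, object$feature_names, drop = FALSE]) - stats::fitted(object)
}

#' @export
plot.activity_kmeans <- function(x, data = NULL, features = NULL, ...) {
  cent <- stats::coef(x)
  feats <- features %||% x$feature_names[seq_len(min(2, length(x$feature_names)))]
  if (length(feats) < 2) stop("need at least two features to plot", call. = FALSE)
  cols <- x$cluster
  if (!is.null(data)) {
    graphics::plot(data[[feats[1]]], data[[feats[2]]], col = cols, pch = 16,
                   cex = 0.6, xlab = feats[1], ylab = feats[2],
                   main = "Activity clusters", ...)
    graphics::points(cent[, feats[1]], cent[, feats[2]], pch = 4, cex = 2, lwd = 3)
    if (!is.null(x$labels))
      graphics::legend("topleft", legend = x$labels,
                       col = seq_len(x$k), pch = 16, bty = "n")
  } else {
    graphics::plot(cent[, feats[1]], cent[, feats[2]], pch = 4, cex = 2, lwd = 3,
                   xlab = feats[1], ylab = feats[2], main = "Cluster centroids", ...)
  }
  invisible(x)
}
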