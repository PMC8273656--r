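#' k-means clustering of the feature matrix
#'
#' Partitions the (cn, rdsd) points into `k` clusters by Euclidean k-means
#' (`stats::kmeans`, multiple random restarts under a fixed seed, so runs
#' are deterministic). If fewer than `k` distinct points exist, `k` is
#' lowered to that count with a warning.
#'
#' @param features A `cbcnv_features` object (or a 2-column numeric matrix).
#' @param k Number of clusters.
#' @param seed RNG seed for the restarts.
#' @param nstart Number of random restarts.
#' @return A list with `assignments` (integer cluster id per segment),
#'   `centers` (k x 2 matrix) and `k` (possibly lowered).
#' @export
cluster_features <- function(features, k = 5, seed = 0, nstart = 10) {
  pts <- feature_points(features)
  if (nrow(pts) == 0L) stop("empty feature matrix", call. = FALSE)
  n_distinct <- nrow(unique(pts))
  if (n_distinct < k) {
    warning(sprintf("only %d distinct points; lowering k from %d", n_distinct, k),
            call. = FALSE)
    k <- n_distinct
  }
  if (k == 1L) {
    return(list(assignments = rep(1L, nrow(pts)),
                centers = matrix(colMeans(pts), nrow = 1,
                                 dimnames = list(NULL, colnames(pts))),
                k = 1L))
  }
  km <- with_seed(seed, stats::kmeans(pts, centers = k, nstart = nstart,
                                      iter.max = 100))
  list(assignments = as.integer(km$cluster), centers = km$centers, k = k)
}

feature_points <- function(features) {
  if (inherits(features, "cbcnv_features")) {
    as.matrix(features[, c("cn", "rdsd")])
  } else {
    m <- as.matrix(features)
    colnames(m) <- c("cn", "rdsd")[seq_len(ncol(m))]
    m
  }
}

#' Split clusters into large and small by size
#'
#' Given cluster sizes sorted in descending order, returns the boundary
#' index `theta`: clusters `1..theta` are large, the rest small. The default
#' rule scans `theta = 1..k-1` for the smallest index satisfying both the
#' cumulative-mass rule (the large clusters hold at least a fraction `x` of
#' all points) and the size-gap rule (the smallest large cluster is at
#' least `y` times the largest small cluster). If no such index exists the
#' mass rule alone decides (possibly `theta = k`, meaning no small
#' clusters); with `strict = TRUE` joint unsatisfiability is an error
#' instead.
#'
#' @param sizes_desc Positive cluster sizes, non-increasing.
#' @param x Large-cluster cumulative mass ratio (default 0.9).
#' @param y Size-ratio multiple (default 5).
#' @param strict Error when no `theta < k` satisfies both rules.
#' @return The boundary index `theta` in `1..k`.
#' @examples
#' partition_large_small(c(90, 5, 5))            # 1
#' partition_large_small(c(100))                 # 1 (no small clusters)
#' partition_large_small(c(50, 30, 10, 5, 5))    # 3 (mass-rule fallback)
#' @export
partition_large_small <- function(sizes_desc, x = 0.9, y = 5, strict = FALSE) {
  k <- length(sizes_desc)
  if (k == 0L) stop("empty cluster size vector", call. = FALSE)
  if (any(sizes_desc <= 0)) stop("cluster sizes must be positive", call. = FALSE)
  if (is.unsorted(rev(sizes_desc))) {
    stop("'sizes_desc' must be non-increasing", call. = FALSE)
  }
  total <- sum(sizes_desc)
  csum <- cumsum(sizes_desc)
  if (k > 1L) {
    for (theta in seq_len(k - 1L)) {
      if (csum[theta] >= x * total &&
          sizes_desc[theta] / sizes_desc[theta + 1L] >= y) {
        return(theta)
      }
    }
  }
  if (strict && k > 1L) {
    stop("no boundary satisfies both the mass and size-gap rules", call. = FALSE)
  }
  # mass rule alone
  which(csum >= x * total)[1L]
}

#' Cluster-based abnormal scores (CBAS)
#'
#' Scores each feature point by its distance to the governing large-cluster
#' center: a point in a small cluster scores the Euclidean distance to the
#' *nearest* large cluster's center; a point in a large cluster scores the
#' distance to its own cluster's center. Zero therefore means the point
#' sits exactly on a large-cluster center; large scores flag segments whose
#' (cn, rdsd) position is far from the bulk of the profile.
#'
#' @param features A `cbcnv_features` object (or 2-column matrix).
#' @param assignments Integer cluster id per point.
#' @param centers k x 2 matrix of cluster centers.
#' @param theta Large/small boundary index over the size-sorted clusters
#'   (see [partition_large_small()]).
#' @param order_desc Cluster ids sorted by decreasing size (stable in id for
#'   ties); computed from `assignments` when `NULL`.
#' @return Numeric vector of non-negative scores, one per point.
#' @export
cbas_scores <- function(features, assignments, centers, theta,
                        order_desc = NULL) {
  pts <- feature_points(features)
  k <- nrow(centers)
  if (is.null(order_desc)) {
    sizes <- tabulate(assignments, nbins = k)
    order_desc <- order(-sizes, seq_len(k))
  }
  if (theta < 1L || theta > k) stop("'theta' must be in 1..k", call. = FALSE)
  large_ids <- order_desc[seq_len(theta)]
  is_small_cluster <- !(seq_len(k) %in% large_ids)
  large_centers <- centers[large_ids, , drop = FALSE]

  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cl <- assignments[i]
    if (is_small_cluster[cl]) {
      d <- sqrt(rowSums((large_centers -
                           matrix(pts[i, ], nrow(large_centers), 2,
                                  byrow = TRUE))^2))
      scores[i] <- min(d)
    } else {
      scores[i] <- sqrt(sum((pts[i, ] - centers[cl, ])^2))
    }
  }
  scores
}

#' Fit the full cluster-score model for a segment profile
#'
#' Convenience wrapper: clusters the features, splits large/small clusters,
#' and computes per-segment abnormal scores.
#'
#' @inheritParams cluster_features
#' @inheritParams partition_large_small
#' @return An object of class `cbcnv_scores`: a list with `assignments`,
#'   `centers`, `sizes_desc`, `order_desc`, `theta`, `is_small` (per
#'   segment) and `cbas` (per segment).
#' @export
cluster_score_model <- function(features, k = 5, x = 0.9, y = 5, seed = 0,
                                nstart = 10, strict = FALSE) {
  cl <- cluster_features(features, k = k, seed = seed, nstart = nstart)
  sizes <- tabulate(cl$assignments, nbins = cl$k)
  order_desc <- order(-sizes, seq_len(cl$k))
  sizes_desc <- sizes[order_desc]
  theta <- partition_large_small(sizes_desc, x = x, y = y, strict = strict)
  scores <- cbas_scores(features, cl$assignments, cl$centers, theta,
                        order_desc = order_desc)
  large_ids <- order_desc[seq_len(theta)]
  out <- list(assignments = cl$assignments, centers = cl$centers,
              k = cl$k, sizes_desc = sizes_desc, order_desc = order_desc,
              theta = theta,
              is_small = !(cl$assignments %in% large_ids),
              cbas = scores)
  class(out) <- "cbcnv_scores"
  out
}

#' @export
print.cbcnv_scores <- function(x, ...) {
  cat(sprintf("Cluster score model: k = %d, theta = %d (%d large / %d small clusters)\n",
              x$k, x$theta, x$theta, x$k - x$theta))
  cat(sprintf("  CBAS range: [%.4g, %.4g] over %d segments (%d in small clusters)\n",
              min(x$cbas), max(x$cbas), length(x$cbas), sum(x$is_small)))
  invisible(x)
}
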