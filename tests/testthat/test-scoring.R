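test_that("k-means wrapper: trivial k, separated clouds, SSE near brute force", {
  set.seed(3)
  pts <- cbind(cn = rnorm(12, 2, 0.1), rdsd = rnorm(12, 0, 0.1))
  one <- cluster_features(pts, k = 1)
  expect_equal(one$assignments, rep(1L, 12))
  expect_equal(unname(one$centers[1, ]), unname(colMeans(pts)))

  # three well-separated clouds are recovered exactly
  clouds <- rbind(matrix(rnorm(20, 0, 0.05), ncol = 2),
                  matrix(rnorm(20, 10, 0.05), ncol = 2),
                  matrix(rnorm(20, 20, 0.05), ncol = 2))
  cl <- cluster_features(clouds, k = 3, seed = 1)
  lab <- rep(1:3, each = 10)
  expect_equal(length(unique(paste(cl$assignments, lab))), 3L)

  # within-cluster SSE is (near) the exhaustive optimum on a tiny instance
  small <- matrix(runif(16, 0, 5), ncol = 2)
  fit <- cluster_features(small, k = 3, seed = 2, nstart = 50)
  sse <- sum(sapply(1:3, function(c) {
    sub <- small[fit$assignments == c, , drop = FALSE]
    if (nrow(sub) == 0) 0 else sum(sweep(sub, 2, colMeans(sub))^2)
  }))
  expect_lte(sse, brute_force_min_sse(small, 3) + 1e-8)

  # fewer distinct points than k lowers k with a warning
  dup <- matrix(rep(c(1, 2), each = 6), ncol = 2)
  expect_warning(red <- cluster_features(dup, k = 5), "lowering k")
  expect_equal(red$k, 1L)
  expect_error(cluster_features(matrix(numeric(0), ncol = 2), k = 2), "empty")
})

test_that("large/small boundary follows the mass and size-gap rules", {
  expect_equal(partition_large_small(c(90, 5, 5), x = 0.9, y = 5), 1L)
  expect_equal(partition_large_small(c(100)), 1L)
  # both rules jointly unsatisfiable below k -> mass-rule fallback
  expect_equal(partition_large_small(c(50, 30, 10, 5, 5), x = 0.9, y = 5), 3L)
  expect_error(partition_large_small(c(50, 30, 10, 5, 5), strict = TRUE),
               "no boundary")
  expect_error(partition_large_small(numeric(0)), "empty")
  expect_error(partition_large_small(c(5, 90)), "non-increasing")
  # theta = k means every cluster is large (empty small set)
  expect_equal(partition_large_small(c(60, 40), x = 0.9, y = 5), 2L)
})

test_that("abnormal scores follow the two-case center-distance definition", {
  centers <- rbind(c(2, 0), c(4, 0), c(2, 1))
  # cluster sizes 10, 8, 1 -> theta = 2 leaves cluster 3 small
  assignments <- c(rep(1L, 10), rep(2L, 8), 3L)
  pts <- rbind(matrix(rep(c(2, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(4, 0), 8), ncol = 2, byrow = TRUE),
               c(2, 1))
  s <- cbas_scores(pts, assignments, centers, theta = 2)
  expect_equal(s[1], 0)                   # on its large-cluster center
  expect_equal(s[19], 1)                  # min(1, sqrt(5)) to large centers
  expect_true(all(s >= 0))
})

test_that("abnormal scores match the explicit-loop oracle on random instances", {
  set.seed(29)
  for (rep in 1:10) {
    n <- 50
    pts <- cbind(runif(n, 0, 4), runif(n, 0, 2))
    cl <- cluster_features(pts, k = 4, seed = rep)
    sizes <- tabulate(cl$assignments, nbins = cl$k)
    ord <- order(-sizes, seq_len(cl$k))
    theta <- partition_large_small(sizes[ord], x = 0.9, y = 5)
    expect_equal(
      cbas_scores(pts, cl$assignments, cl$centers, theta, order_desc = ord),
      naive_cbas(pts, cl$assignments, cl$centers, theta),
      tolerance = 1e-12)
  }
})

test_that("scores are translation invariant and maximal for a planted extreme", {
  set.seed(37)
  pts <- cbind(rnorm(60, 2, 0.1), rnorm(60, 0.1, 0.02))
  pts[60, ] <- c(9, 1.5)  # one extreme segment
  m1 <- cluster_score_model(pts, k = 4, seed = 1)
  shifted <- sweep(pts, 2, c(3.7, -1.2), "+")
  m2 <- cluster_score_model(shifted, k = 4, seed = 1)
  expect_equal(m1$cbas, m2$cbas, tolerance = 1e-8)
  expect_equal(which.max(m1$cbas), 60L)
})

test_that("the fitted model partitions all segments and reports a valid theta", {
  set.seed(43)
  pts <- cbind(c(rnorm(90, 2, 0.05), rnorm(5, 4, 0.05), rnorm(5, 0.8, 0.05)),
               c(rnorm(90, 0, 0.02), rnorm(5, 0.4, 0.02), rnorm(5, 0.4, 0.02)))
  m <- cluster_score_model(pts, k = 3, x = 0.9, y = 5, seed = 0)
  expect_equal(length(m$assignments), 100L)
  expect_true(all(m$assignments %in% seq_len(m$k)))
  expect_true(m$theta >= 1 && m$theta <= m$k)
  expect_false(is.unsorted(rev(m$sizes_desc)))
  # the dominant diploid cloud is the large cluster; outliers are small
  expect_equal(m$theta, 1L)
  expect_true(all(m$is_small[91:100]))
  expect_false(any(m$is_small[1:90]))
})
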