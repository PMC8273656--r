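# Independent brute-force oracles used by the tests. Each is written from
# the definitions directly (explicit loops, per-base counting, dual QP) and
# shares no code with the package implementation it checks.

# Neighborhood mean absolute ratio difference: literal double loop over the
# five positional window cases.
naive_rdsd <- function(r, L) {
  n <- length(r)
  out <- numeric(n)
  for (i in 1:n) {
    js <- integer(0)
    if (i == 1) {
      for (j in (i + 1):min(i + L, n)) js <- c(js, j)
    } else if (i <= L) {
      for (j in 1:min(i + L, n)) if (j != i) js <- c(js, j)
    } else if (i <= n - L) {
      for (j in (i - L):(i + L)) if (j != i) js <- c(js, j)
    } else if (i <= n - 1) {
      for (j in max(1, i - L):(n - 1)) if (j != i) js <- c(js, j)
    } else {
      for (j in max(1, i - L):(i - 1)) js <- c(js, j)
    }
    acc <- 0
    for (j in js) acc <- acc + abs(r[i] - r[j])
    out[i] <- acc / length(js)
  }
  out
}

# Cluster-based abnormal score: explicit loops over points and centers.
naive_cbas <- function(pts, assignments, centers, theta) {
  k <- nrow(centers)
  sizes <- sapply(1:k, function(c) sum(assignments == c))
  ord <- order(-sizes, 1:k)
  large <- ord[1:theta]
  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cl <- assignments[i]
    if (cl %in% large) {
      scores[i] <- sqrt(sum((pts[i, ] - centers[cl, ])^2))
    } else {
      best <- Inf
      for (g in large) {
        d <- sqrt(sum((pts[i, ] - centers[g, ])^2))
        if (d < best) best <- d
      }
      scores[i] <- best
    }
  }
  scores
}

# Exact fused-lasso solution via the box-constrained dual QP:
# L-BFGS-B to get close, then exact coordinate descent to machine precision.
tv_dual_oracle <- function(y, lambda, sweeps = 50000) {
  n <- length(y)
  if (n < 2 || lambda == 0) return(y)
  Dt <- function(z) {
    b <- numeric(n)
    b[1] <- -z[1]
    if (n > 2) b[2:(n - 1)] <- z[1:(n - 2)] - z[2:(n - 1)]
    b[n] <- z[n - 1]
    b
  }
  fn <- function(z) { b <- y - Dt(z); 0.5 * sum(b^2) }
  gr <- function(z) { b <- y - Dt(z); -(b[2:n] - b[1:(n - 1)]) }
  o <- stats::optim(numeric(n - 1), fn, gr, method = "L-BFGS-B",
                    lower = -lambda, upper = lambda,
                    control = list(maxit = 50000, factr = 10))
  z <- o$par
  b <- y - Dt(z)
  for (s in seq_len(sweeps)) {
    delta_max <- 0
    for (i in seq_len(n - 1)) {
      znew <- min(lambda, max(-lambda, z[i] + (b[i + 1] - b[i]) / 2))
      d <- znew - z[i]
      if (d != 0) {
        z[i] <- znew
        b[i] <- b[i] + d
        b[i + 1] <- b[i + 1] - d
        delta_max <- max(delta_max, abs(d))
      }
    }
    if (delta_max < 1e-14) break
  }
  b
}

# Overlap matching by literal per-base membership counting (bp resolution).
perbase_overlap_match <- function(cs, ce, ts, te, frac = 0.5) {
  call_bases <- seq.int(cs, ce - 1)
  truth_bases <- seq.int(ts, te - 1)
  covered <- sum(truth_bases %in% call_bases)
  covered / length(truth_bases) > frac
}

# Minimal within-cluster SSE over all k-labelings of tiny point sets.
brute_force_min_sse <- function(pts, k) {
  n <- nrow(pts)
  best <- Inf
  labelings <- expand.grid(rep(list(1:k), n))
  for (r in seq_len(nrow(labelings))) {
    lab <- as.integer(labelings[r, ])
    sse <- 0
    for (c in unique(lab)) {
      sub <- pts[lab == c, , drop = FALSE]
      ctr <- colMeans(sub)
      sse <- sse + sum(sweep(sub, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# Small default simulation scaled down for fast unit tests.
tiny_sim_config <- function(...) {
  sim_config(genome_length = 4e6, n_regions = 6, gain_count = 3,
             het_loss_count = 1, hom_loss_count = 2,
             length_levels = c(1e4, 3e4, 5e4), length_range = c(1e4, 5e4),
             ...)
}
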