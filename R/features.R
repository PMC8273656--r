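#' Per-segment copy number estimates
#'
#' \eqn{CN_i = CN_{norm} \cdot RDS_i / RDS_m} with \eqn{CN_{norm} = 2}: a
#' segment at the global mean depth maps to the diploid copy number 2 and
#' copy number scales linearly with relative depth.
#'
#' @param segments A `cbcnv_segments` object, or a numeric vector of segment
#'   values with `rds_m` supplied.
#' @param rds_m Global mean segment depth; taken from `segments` when absent.
#' @param cn_norm Baseline copy number (2).
#' @return Numeric vector of copy-number estimates.
#' @export
compute_cn <- function(segments, rds_m = NULL, cn_norm = 2) {
  cn_norm * compute_rdsr(segments, rds_m)
}

#' Per-segment depth ratios
#'
#' \eqn{RDSR_i = RDS_i / RDS_m}; the copy-number estimate is
#' `2 * compute_rdsr(...)`.
#'
#' @inheritParams compute_cn
#' @return Numeric vector of ratios.
#' @export
compute_rdsr <- function(segments, rds_m = NULL) {
  if (inherits(segments, "cbcnv_segments")) {
    values <- segments$value
    if (is.null(rds_m)) rds_m <- attr(segments, "rds_m")
  } else {
    values <- as.numeric(segments)
    if (is.null(rds_m)) rds_m <- mean(values)
  }
  stopifnot_scalar_number(rds_m, "rds_m")
  if (rds_m <= 0) stop("'rds_m' must be positive (degenerate profile)", call. = FALSE)
  values / rds_m
}

#' Neighborhood mean absolute ratio differences (RDSD)
#'
#' For each segment ratio \eqn{RDSR_i}, the mean absolute difference to its
#' windowed neighbors, with five positional cases over a half-width `L`:
#' \itemize{
#'   \item `i = 1`: the `L` right neighbors (denominator `L`);
#'   \item `1 < i <= L`: neighbors `1..i+L` excluding self (denominator
#'     `i - 1 + L`);
#'   \item `L < i <= n - L`: neighbors `i-L..i+L` (the self term is zero;
#'     denominator `2L`);
#'   \item `n - L < i <= n - 1`: neighbors `i-L..n-1` excluding self
#'     (denominator `L + n - i - 1`; the last element is excluded by the
#'     window definition);
#'   \item `i = n`: the `L` left neighbors (denominator `L`).
#' }
#' For profiles shorter than the windows assume (`n <= 2L`), window ranges
#' are clipped to existing indices and denominators count the actual
#' neighbor terms; case precedence follows the order above.
#'
#' @param rdsr Numeric ratio vector (length >= 2).
#' @param L Neighbor half-width, in `[5, 20]` by default (`allow_any_L`
#'   lifts the bound).
#' @param allow_any_L Permit `L` outside `[5, 20]`.
#' @return Numeric vector of non-negative neighborhood deviations.
#' @export
compute_rdsd <- function(rdsr, L = 10, allow_any_L = FALSE) {
  n <- length(rdsr)
  if (n < 2L) stop("need at least 2 segments for RDSD", call. = FALSE)
  L <- as.integer(L)
  if (!allow_any_L && (L < 5L || L > 20L)) {
    stop("'L' must be in [5, 20] (set allow_any_L = TRUE to override)",
         call. = FALSE)
  }
  if (L < 1L) stop("'L' must be >= 1", call. = FALSE)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L) {
      w <- seq.int(2L, min(1L + L, n))
    } else if (i <= L) {
      w <- seq.int(1L, min(i + L, n))
    } else if (i <= n - L) {
      w <- seq.int(i - L, i + L)
    } else if (i <= n - 1L) {
      w <- seq.int(max(1L, i - L), n - 1L)
    } else {
      w <- seq.int(max(1L, i - L), i - 1L)
    }
    w <- w[w != i]
    out[i] <- sum(abs(rdsr[i] - rdsr[w])) / length(w)
  }
  out
}

#' Two-dimensional feature embedding of a segment profile
#'
#' Pairs each segment's copy-number estimate with its neighborhood ratio
#' deviation: the point set \{(CN_i, RDSD_i)\} that is clustered and scored
#' downstream.
#'
#' @param segments A `cbcnv_segments` object.
#' @param L Neighbor half-width for [compute_rdsd()].
#' @param standardize Standardize both columns to unit variance before
#'   clustering (off by default; the raw features are used as-is).
#' @param allow_any_L Passed to [compute_rdsd()].
#' @return An object of class `cbcnv_features`: a data frame with columns
#'   `segment`, `cn`, `rdsd` in segment order, with `L` as an attribute.
#' @export
build_feature_matrix <- function(segments, L = 10, standardize = FALSE,
                                 allow_any_L = FALSE) {
  stopifnot(inherits(segments, "cbcnv_segments"))
  rdsr <- compute_rdsr(segments)
  cn <- 2 * rdsr
  rdsd <- compute_rdsd(rdsr, L = L, allow_any_L = allow_any_L)
  if (standardize) {
    sdz <- function(v) if (stats::sd(v) > 0) v / stats::sd(v) else v
    cn <- sdz(cn)
    rdsd <- sdz(rdsd)
  }
  out <- data.frame(segment = seq_along(cn), cn = cn, rdsd = rdsd)
  attr(out, "L") <- L
  class(out) <- c("cbcnv_features", "data.frame")
  out
}
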