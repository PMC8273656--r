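#' Build a binned read-depth profile with GC fractions and N-masking
#'
#' Divides one chromosome into contiguous, non-overlapping, constant-width
#' bins (a trailing short bin is dropped) and attaches per-bin read depth,
#' GC fraction and an N-mask. Bins containing at least one ambiguous 'N'
#' reference base are flagged abnormal and excluded from every downstream
#' statistic.
#'
#' Two count dialects are accepted:
#' \itemize{
#'   \item per-base: columns `chrom`, `pos` (1-based), `count`; bin depth is
#'     the mean per-base count over the bin;
#'   \item per-bin: columns `chrom`, `bin_start`, `bin_end` (0-based
#'     half-open), `count`; the bin count is used as the depth directly.
#' }
#'
#' The reference may be a `Biostrings::DNAStringSet`/`DNAString`, a plain
#' character sequence, or `NULL` with per-bin `gc` (and optionally
#' `n_masked`) supplied instead — the form emitted by [simulate_pair()].
#'
#' @param counts Count table in one of the two dialects above.
#' @param reference Reference sequence for the chromosome, or `NULL`.
#' @param bin_size Bin width in bp.
#' @param gc Per-bin GC fractions (used when `reference` is `NULL`).
#' @param n_masked Optional logical per-bin mask (used when `reference` is
#'   `NULL`; defaults to no masking).
#' @return An object of class `cbcnv_profile`: a data frame with columns
#'   `chrom`, `start`, `end`, `depth`, `gc`, `n_masked`, carrying `bin_size`
#'   as an attribute. Masked bins are retained in the table (flagged) but
#'   ignored by all downstream operations.
#' @export
bin_and_mask <- function(counts, reference = NULL, bin_size = 2000,
                         gc = NULL, n_masked = NULL) {
  stopifnot_scalar_number(bin_size, "bin_size")
  per_base <- all(c("pos", "count") %in% names(counts))
  per_bin <- all(c("bin_start", "bin_end", "count") %in% names(counts))
  if (!per_base && !per_bin) {
    stop("counts must have columns (chrom, pos, count) or (chrom, bin_start, bin_end, count)",
         call. = FALSE)
  }
  chrom <- if ("chrom" %in% names(counts)) counts$chrom[1] else "chr"

  if (per_bin && !per_base) {
    widths <- counts$bin_end - counts$bin_start
    if (length(unique(widths)) > 1L) {
      counts <- counts[widths == bin_size, , drop = FALSE]
    }
    if (any(counts$bin_end - counts$bin_start != bin_size)) {
      stop("per-bin counts do not match 'bin_size'", call. = FALSE)
    }
    starts <- counts$bin_start
    depth <- as.numeric(counts$count)
  } else {
    if (is.unsorted(counts$pos)) {
      stop("per-base counts must be sorted by position", call. = FALSE)
    }
    span <- max(counts$pos)
    if (!is.null(reference)) {
      ref_len <- reference_length(reference)
      if (span > ref_len) {
        stop("count positions extend beyond the reference length", call. = FALSE)
      }
      span <- ref_len
    }
    n_bins <- floor(span / bin_size)
    if (n_bins < 1L) stop("no complete bin fits the input", call. = FALSE)
    bin_of <- floor((counts$pos - 1) / bin_size) + 1
    keep <- bin_of <= n_bins
    depth <- as.numeric(tapply(
      counts$count[keep],
      factor(bin_of[keep], levels = seq_len(n_bins)),
      sum, default = 0)) / bin_size
    depth[is.na(depth)] <- 0
    starts <- (seq_len(n_bins) - 1) * bin_size
  }

  n_bins <- length(depth)
  if (!is.null(reference)) {
    rg <- reference_gc_mask(reference, n_bins, bin_size)
    gc <- rg$gc
    n_masked <- rg$n_masked
  } else {
    if (is.null(gc)) stop("supply 'reference' or per-bin 'gc'", call. = FALSE)
    if (length(gc) != n_bins) {
      stop("'gc' must have one value per complete bin", call. = FALSE)
    }
    if (is.null(n_masked)) n_masked <- rep(FALSE, n_bins)
  }

  out <- data.frame(chrom = chrom, start = starts, end = starts + bin_size,
                    depth = depth, gc = gc, n_masked = as.logical(n_masked),
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bin_size
  class(out) <- c("cbcnv_profile", "data.frame")
  out
}

reference_length <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(Biostrings::width(reference)[1])
  if (inherits(reference, "DNAString")) return(length(reference))
  nchar(as.character(reference)[1])
}

# per-bin GC fraction over non-N bases and N-mask from a reference sequence
reference_gc_mask <- function(reference, n_bins, bin_size) {
  if (is.character(reference)) {
    reference <- Biostrings::DNAString(reference[1])
  }
  if (inherits(reference, "DNAStringSet")) reference <- reference[[1]]
  gc <- numeric(n_bins)
  n_masked <- logical(n_bins)
  views <- Biostrings::Views(reference,
                             start = (seq_len(n_bins) - 1) * bin_size + 1,
                             width = bin_size)
  freq <- Biostrings::alphabetFrequency(views, baseOnly = TRUE)
  n_count <- freq[, "other"]
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  n_masked <- n_count > 0
  gc <- ifelse(acgt > 0,
               rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
  list(gc = gc, n_masked = n_masked)
}

#' Correct GC content bias in a binned read-depth profile
#'
#' Rescales each bin's depth by the ratio of the global mean depth to the
#' mean depth of that bin's GC stratum:
#' \deqn{RD'_i = RD_i \cdot RD_m / RD_{gc},}
#' where \eqn{RD_m} is the mean depth over all unmasked bins and
#' \eqn{RD_{gc}} the mean over bins sharing bin *i*'s GC content. GC
#' fractions are rounded to the nearest 0.01 to define strata. After
#' correction every stratum's mean equals \eqn{RD_m}, so the global mean is
#' preserved. A stratum with zero mean depth cannot be rescaled; its bins
#' are masked with a warning.
#'
#' @param profile A `cbcnv_profile` from [bin_and_mask()].
#' @return The profile with corrected `depth` (masked bins untouched).
#' @export
gc_correct <- function(profile) {
  stopifnot(inherits(profile, "cbcnv_profile"))
  ok <- !profile$n_masked
  if (!any(ok)) stop("no unmasked bins to correct", call. = FALSE)
  stratum <- round(profile$gc, 2)
  rd_m <- mean(profile$depth[ok])
  rd_gc <- stats::ave(profile$depth[ok], stratum[ok], FUN = mean)
  zero <- rd_gc == 0
  if (any(zero)) {
    warning(sprintf("%d bins in zero-depth GC strata masked", sum(zero)),
            call. = FALSE)
    idx <- which(ok)[zero]
    profile$n_masked[idx] <- TRUE
    ok2 <- which(ok)[!zero]
    profile$depth[ok2] <- profile$depth[ok2] * rd_m / rd_gc[!zero]
  } else {
    profile$depth[ok] <- profile$depth[ok] * rd_m / rd_gc
  }
  profile
}

#' Default fusion penalty for segmentation
#'
#' \eqn{\lambda = 2 \hat\sigma \sqrt{\log n}} with \eqn{\hat\sigma} the
#' median absolute deviation of first differences divided by \eqn{\sqrt 2}
#' — a universal-threshold style choice that scales with the noise level of
#' the depth profile.
#'
#' @param y Numeric signal.
#' @return A non-negative penalty.
#' @export
default_lambda <- function(y) {
  sigma <- stats::mad(diff(y)) / sqrt(2)
  2 * sigma * sqrt(log(length(y)))
}

#' Denoise and segment a read-depth profile with the fused lasso
#'
#' Fits the exact 1-D fused-lasso problem (see [tv_denoise()]) to the
#' unmasked bin depths and converts maximal runs of equal fitted values into
#' read-depth segments. The segment value is the fitted level (equal to the
#' run's data mean up to total-variation shrinkage at the boundaries).
#'
#' @param profile A `cbcnv_profile`, typically after [gc_correct()].
#' @param lambda Fusion penalty; `NULL` uses [default_lambda()].
#' @param rds_m_weighting `"bin"` (default) computes the global segment mean
#'   \eqn{RDS_m} weighting each segment by its bin count (equals the mean of
#'   the fitted bin values, invariant to arbitrary segment splits);
#'   `"segment"` weights each segment equally.
#' @return An object of class `cbcnv_segments`: a data frame with one row
#'   per segment (`chrom`, `start`, `end` in bp; `first_bin`, `last_bin`
#'   indices into the unmasked bins; `n_bins`; `value`), with attributes
#'   `rds_m` (global mean depth over segments), `lambda`, `fitted` (per
#'   unmasked bin), `bin_depth` (input depths of unmasked bins) and
#'   `bin_size`.
#' @export
denoise_and_segment <- function(profile, lambda = NULL,
                                rds_m_weighting = c("bin", "segment")) {
  stopifnot(inherits(profile, "cbcnv_profile"))
  rds_m_weighting <- match.arg(rds_m_weighting)
  ok <- !profile$n_masked
  if (sum(ok) < 2L) stop("need at least 2 unmasked bins", call. = FALSE)
  y <- profile$depth[ok]
  if (is.null(lambda)) lambda <- default_lambda(y)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  fit <- tv_denoise(y, lambda)
  if (lambda == 0) {
    # unpenalized fit: nothing is fused, every bin is its own segment even
    # where neighboring data values happen to coincide
    runs <- list(lengths = rep(1L, length(fit)), values = fit)
  } else {
    runs <- rle(fit)
  }
  last <- cumsum(runs$lengths)
  first <- last - runs$lengths + 1L
  starts <- profile$start[ok]
  ends <- profile$end[ok]
  seg <- data.frame(chrom = profile$chrom[1],
                    start = starts[first], end = ends[last],
                    first_bin = first, last_bin = last,
                    n_bins = runs$lengths, value = runs$values,
                    stringsAsFactors = FALSE)
  rds_m <- if (rds_m_weighting == "bin") {
    weighted_mean_by_bins(seg$value, seg$n_bins)
  } else {
    mean(seg$value)
  }
  attr(seg, "rds_m") <- rds_m
  attr(seg, "lambda") <- lambda
  attr(seg, "fitted") <- fit
  attr(seg, "bin_depth") <- y
  attr(seg, "bin_size") <- attr(profile, "bin_size")
  class(seg) <- c("cbcnv_segments", "data.frame")
  seg
}
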