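#' Detect CNVs in a tumor-normal matched read-depth pair
#'
#' Runs the full cluster-based CNV detection pipeline on binned read counts
#' of a tumor sample and (optionally) its matched normal:
#' \enumerate{
#'   \item bin the counts, mask bins touching ambiguous reference bases;
#'   \item correct GC content bias ([gc_correct()]);
#'   \item denoise/segment the depth profile with an exact fused-lasso fit
#'     ([denoise_and_segment()]);
#'   \item embed each segment as a 2-D point (copy-number estimate,
#'     neighborhood ratio deviation; [build_feature_matrix()]);
#'   \item k-means cluster the points, split clusters into large/small and
#'     score each segment by its distance to the governing large-cluster
#'     center ([cluster_score_model()]);
#'   \item call segments above Tukey's upper fence, merge adjacent flagged
#'     segments, type calls gain/loss against the normal-segment baseline,
#'     and classify them somatic/germline by reciprocal overlap with the
#'     matched-normal call set ([tukey_threshold()], [call_cnvs()],
#'     [assign_gain_loss()], [classify_origin()]).
#' }
#' Tumor and normal samples are each preprocessed and scored independently;
#' the matched normal enters only through the germline classification.
#'
#' @param tumor Tumor count table (see [bin_and_mask()] for dialects).
#' @param normal Matched normal count table, or `NULL` (no origin
#'   classification).
#' @param reference Reference sequence (FASTA contents via
#'   `Biostrings::readDNAStringSet`, a `DNAString`, or a character string),
#'   or `NULL` with `gc` supplied.
#' @param gc Per-bin GC fractions when no reference is given.
#' @param bin_size Bin width in bp (default 2000).
#' @param lambda Fused-lasso penalty; `NULL` selects [default_lambda()].
#' @param L Neighbor half-width of the RDSD feature (default 10).
#' @param k Number of k-means clusters (default 5).
#' @param x Large-cluster cumulative mass ratio (default 0.9).
#' @param y Large/small size-ratio multiple (default 5).
#' @param w Tukey's fences abnormal weight (default 1.5).
#' @param seed RNG seed for the clustering restarts (default 0).
#' @param merge Merge adjacent flagged segments into single calls.
#' @param min_overlap Reciprocal overlap for germline classification.
#' @return An object of class `cbcnv`: list with `calls` (tumor CNV calls:
#'   `chrom`, `start`, `end`, `type`, `origin`, `cbas`, `mean_rd`),
#'   `normal_calls`, `tumor`/`normal` per-sample sub-results (profile,
#'   segments, features, scores, fence) and the parameter set `params`.
#' @examples
#' sim <- simulate_pair(sim_config(genome_length = 2e6, n_regions = 4,
#'                                 gain_count = 2, het_loss_count = 1,
#'                                 hom_loss_count = 1, purity = 1), seed = 1)
#' fit <- cbcnv(sim$tumor, sim$normal, gc = sim$gc)
#' fit
#' @export
cbcnv <- function(tumor, normal = NULL, reference = NULL, gc = NULL,
                  bin_size = 2000, lambda = NULL, L = 10, k = 5,
                  x = 0.9, y = 5, w = 1.5, seed = 0, merge = TRUE,
                  min_overlap = 0.5) {
  run_sample <- function(counts) {
    profile <- bin_and_mask(counts, reference = reference,
                            bin_size = bin_size, gc = gc)
    profile <- gc_correct(profile)
    segments <- denoise_and_segment(profile, lambda = lambda)
    res <- list(profile = profile, segments = segments,
                features = NULL, scores = NULL, fence = NULL,
                calls = empty_calls())
    if (nrow(segments) < max(4L, 2L)) {
      warning("fewer than 4 segments; no calls made for this sample",
              call. = FALSE)
      return(res)
    }
    res$features <- build_feature_matrix(segments, L = L)
    res$scores <- cluster_score_model(res$features, k = k, x = x, y = y,
                                      seed = seed)
    res$fence <- tukey_threshold(res$scores$cbas, w = w)
    calls <- call_cnvs(segments, res$scores, res$fence, merge = merge)
    if (nrow(calls) > 0 && nrow(calls) < nrow(segments)) {
      calls <- assign_gain_loss(calls, segments)
    } else if (nrow(calls) > 0) {
      calls$type <- NA_character_
    }
    res$calls <- calls
    res
  }

  tumor_res <- run_sample(tumor)
  normal_res <- if (!is.null(normal)) run_sample(normal) else NULL

  calls <- tumor_res$calls
  if (nrow(calls) > 0) {
    if (!is.null(normal_res)) {
      calls <- classify_origin(calls, normal_res$calls,
                               min_overlap = min_overlap)
    } else {
      calls$origin <- NA_character_
    }
  }

  out <- list(
    calls = calls,
    normal_calls = if (is.null(normal_res)) NULL else normal_res$calls,
    tumor = tumor_res,
    normal = normal_res,
    params = list(bin_size = bin_size,
                  lambda = attr(tumor_res$segments, "lambda"),
                  L = L, k = k, x = x, y = y, w = w, seed = seed,
                  merge = merge, min_overlap = min_overlap)
  )
  class(out) <- "cbcnv"
  out
}

empty_calls <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             cbas = numeric(0), mean_rd = numeric(0),
             first_seg = integer(0), last_seg = integer(0),
             stringsAsFactors = FALSE)
}

#' Extract the CNV calls from a fitted object
#' @param object A `cbcnv` fit.
#' @param ... Unused.
#' @return Data frame of tumor CNV calls.
#' @export
cnv_calls <- function(object, ...) {
  stopifnot(inherits(object, "cbcnv"))
  object$calls
}

#' @export
print.cbcnv <- function(x, ...) {
  p <- x$params
  cat("Cluster-based CNV detection fit\n")
  cat(sprintf("  parameters: bin %d bp, lambda %.3g, L %d, k %d, x %.2f, y %g, w %.2f\n",
              as.integer(p$bin_size), p$lambda, p$L, p$k, p$x, p$y, p$w))
  cat(sprintf("  tumor: %d segments, fence T = %s\n",
              nrow(x$tumor$segments),
              if (is.null(x$tumor$fence)) "NA" else sprintf("%.4g", x$tumor$fence$T)))
  n <- nrow(x$calls)
  cat(sprintf("  calls: %d (%d gain / %d loss; %d somatic / %d germline)\n",
              n, sum(x$calls$type == "gain", na.rm = TRUE),
              sum(x$calls$type == "loss", na.rm = TRUE),
              sum(x$calls$origin == "somatic", na.rm = TRUE),
              sum(x$calls$origin == "germline", na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cbcnv <- function(object, ...) {
  out <- list(params = object$params,
              n_segments = nrow(object$tumor$segments),
              fence = object$tumor$fence,
              theta = if (is.null(object$tumor$scores)) NA_integer_
                      else object$tumor$scores$theta,
              calls = object$calls)
  class(out) <- "summary.cbcnv"
  out
}

#' @export
print.summary.cbcnv <- function(x, ...) {
  cat("Cluster-based CNV detection — summary\n")
  cat(sprintf("  segments: %d; large/small boundary theta = %s\n",
              x$n_segments, x$theta))
  if (!is.null(x$fence)) {
    cat(sprintf("  score fence: Q1 %.4g, Q3 %.4g, w %.2f -> T %.4g\n",
                x$fence$q1, x$fence$q3, x$fence$w, x$fence$T))
  }
  if (nrow(x$calls) == 0) {
    cat("  no CNV calls\n")
  } else {
    cat(sprintf("  %d CNV calls:\n", nrow(x$calls)))
    cols <- intersect(c("chrom", "start", "end", "type", "origin", "cbas"),
                      names(x$calls))
    print(x$calls[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' Plot a fitted CNV profile
#'
#' Shows the GC-corrected bin depths of the tumor sample, the fused-lasso
#' segment means, and shades the called regions (gain red, loss blue).
#'
#' @param x A `cbcnv` fit.
#' @param which `"tumor"` or `"normal"`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cbcnv <- function(x, which = c("tumor", "normal"), ...) {
  which <- match.arg(which)
  res <- x[[which]]
  if (is.null(res)) stop("no ", which, " sample in this fit", call. = FALSE)
  prof <- res$profile
  ok <- !prof$n_masked
  mid <- (prof$start[ok] + prof$end[ok]) / 2
  graphics::plot(mid, prof$depth[ok], pch = ".", col = "grey50",
                 xlab = "position (bp)", ylab = "corrected read depth",
                 main = sprintf("%s read-depth profile", which), ...)
  seg <- res$segments
  graphics::segments(seg$start, seg$value, seg$end, seg$value,
                     col = "black", lwd = 2)
  calls <- if (which == "tumor") x$calls else x$normal_calls
  if (!is.null(calls) && nrow(calls) > 0) {
    cols <- ifelse(calls$type == "gain",
                   grDevices::adjustcolor("red", 0.25),
                   grDevices::adjustcolor("blue", 0.25))
    usr <- graphics::par("usr")
    graphics::rect(calls$start, usr[3], calls$end, usr[4],
                   col = cols, border = NA)
  }
  invisible(x)
}

#' Per-bin residuals of the segmentation fit
#' @param object A `cbcnv` fit.
#' @param which `"tumor"` or `"normal"`.
#' @param ... Unused.
#' @return Numeric vector: corrected depth minus fitted segment value, one
#'   per unmasked bin.
#' @export
residuals.cbcnv <- function(object, which = c("tumor", "normal"), ...) {
  which <- match.arg(which)
  res <- object[[which]]
  attr(res$segments, "bin_depth") - attr(res$segments, "fitted")
}

#' Extract per-bin counts from a BAM file
#'
#' Counts aligned reads (by leftmost position) per fixed-width bin on one
#' chromosome, with an optional mapping-quality filter. Requires the
#' Rsamtools package.
#'
#' @param bam Path to an indexed BAM file.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @param min_mapq Minimum mapping quality (default 0).
#' @return Bin-count data frame (`chrom`, `bin_start`, `bin_end`, `count`)
#'   ready for [cbcnv()] or [bin_and_mask()].
#' @export
bam_bin_counts <- function(bam, chrom, chrom_length, bin_size = 2000,
                           min_mapq = 0) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM input requires the Rsamtools package", call. = FALSE)
  }
  n_bins <- floor(chrom_length / bin_size)
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "mapq"),
    which = GenomicRangesLikeRegion(chrom, n_bins * bin_size),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- !is.na(res$pos) & (is.na(res$mapq) | res$mapq >= min_mapq)
  pos <- res$pos[keep]
  bin_of <- pmin(floor((pos - 1) / bin_size) + 1, n_bins)
  counts <- tabulate(bin_of, nbins = n_bins)
  starts <- (seq_len(n_bins) - 1) * bin_size
  data.frame(chrom = chrom, bin_start = starts, bin_end = starts + bin_size,
             count = counts, stringsAsFactors = FALSE)
}

# small helper kept separate so the Rsamtools stack stays optional
GenomicRangesLikeRegion <- function(chrom, len) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("IRanges", quietly = TRUE)) {
    stop("reading BAM input requires GenomicRanges/IRanges", call. = FALSE)
  }
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = 1, end = len))
}

#' Read a headered bin-count TSV
#' @param path TSV with columns `chrom`, `bin_start`, `bin_end`, `count`.
#' @return Data frame.
#' @export
read_bin_counts <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
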