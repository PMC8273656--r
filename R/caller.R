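#' Tukey's fences threshold on abnormal scores
#'
#' Computes the upper fence \eqn{T = Q_3 + w (Q_3 - Q_1)} over the
#' per-segment abnormal scores. Quartiles use linear interpolation between
#' order statistics (`stats::quantile` type 7). Segments scoring strictly
#' above `T` are declared abnormal.
#'
#' @param scores Numeric CBAS vector (at least 4 values so the quartiles
#'   are well defined).
#' @param w Abnormal weight (default 1.5).
#' @return An object of class `cbcnv_fence`: list with `q1`, `q3`, `w`, `T`.
#' @examples
#' tukey_threshold(c(1, 1, 3, 3))$T  # Q1=1, Q3=3 -> T = 6
#' @export
tukey_threshold <- function(scores, w = 1.5) {
  if (length(scores) < 4L) {
    stop("need at least 4 scores for quartiles; consider a smaller bin size",
         call. = FALSE)
  }
  if (w < 0) stop("'w' must be >= 0", call. = FALSE)
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  out <- list(q1 = q[1], q3 = q[2], w = w, T = q[2] + w * (q[2] - q[1]))
  class(out) <- "cbcnv_fence"
  out
}

#' Call candidate CNVs from scored segments
#'
#' Segments whose abnormal score strictly exceeds the fence `T` become
#' candidate calls; ties go to normal. Runs of consecutive flagged segments
#' are merged into a single call spanning their union (disable with
#' `merge = FALSE`); a merged call's score is the maximum of its members
#' and its depth is the bin-weighted mean of member segment values.
#'
#' @param segments A `cbcnv_segments` object.
#' @param scores CBAS vector aligned to the segments (or a `cbcnv_scores`
#'   object).
#' @param fence A `cbcnv_fence` from [tukey_threshold()].
#' @param merge Merge adjacent flagged segments into one call.
#' @return Data frame of candidate calls: `chrom`, `start`, `end`, `cbas`,
#'   `mean_rd`, `first_seg`, `last_seg`. Zero rows when nothing exceeds `T`.
#' @export
call_cnvs <- function(segments, scores, fence, merge = TRUE) {
  stopifnot(inherits(segments, "cbcnv_segments"))
  if (inherits(scores, "cbcnv_scores")) scores <- scores$cbas
  if (length(scores) != nrow(segments)) {
    stop("'scores' must align with the segments", call. = FALSE)
  }
  flagged <- scores > fence$T
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cbas = numeric(0),
                      mean_rd = numeric(0), first_seg = integer(0),
                      last_seg = integer(0), stringsAsFactors = FALSE)
  if (!any(flagged)) return(empty)
  idx <- which(flagged)
  grp <- if (merge) cumsum(c(1L, diff(idx) != 1L)) else seq_along(idx)
  do.call(rbind, lapply(split(idx, grp), function(ii) {
    data.frame(chrom = segments$chrom[ii[1]],
               start = segments$start[ii[1]],
               end = segments$end[ii[length(ii)]],
               cbas = max(scores[ii]),
               mean_rd = weighted_mean_by_bins(segments$value[ii],
                                               segments$n_bins[ii]),
               first_seg = ii[1], last_seg = ii[length(ii)],
               stringsAsFactors = FALSE)
  }))
}

#' Type candidate calls as gain or loss
#'
#' The baseline is the bin-weighted mean read depth over all *normal*
#' (uncalled) segments. A call whose mean depth is greater than or equal to
#' the baseline is a gain; below it, a loss. Fails if every segment was
#' called (no normal baseline exists).
#'
#' @param calls Candidate calls from [call_cnvs()].
#' @param segments The `cbcnv_segments` the calls were made on.
#' @return `calls` with a `type` column ("gain"/"loss") and the baseline as
#'   attribute `baseline`.
#' @export
assign_gain_loss <- function(calls, segments) {
  stopifnot(inherits(segments, "cbcnv_segments"))
  called <- rep(FALSE, nrow(segments))
  if (nrow(calls) > 0) {
    for (r in seq_len(nrow(calls))) {
      called[calls$first_seg[r]:calls$last_seg[r]] <- TRUE
    }
  }
  if (all(called)) {
    stop("every segment was called; no normal baseline exists", call. = FALSE)
  }
  baseline <- weighted_mean_by_bins(segments$value[!called],
                                    segments$n_bins[!called])
  calls$type <- ifelse(calls$mean_rd >= baseline, "gain", "loss")
  attr(calls, "baseline") <- baseline
  calls
}

#' Classify tumor calls as somatic or germline
#'
#' A CNV present in both the tumor and the matched normal sample is
#' germline; one private to the tumor is somatic. "Present in both" is
#' quantified as at least `min_overlap` reciprocal overlap (intersection
#' covering that fraction of *both* intervals) with some normal-sample call
#' on the same chromosome.
#'
#' @param tumor_calls Typed tumor calls (data frame with `chrom`, `start`,
#'   `end`).
#' @param normal_calls Calls from the matched normal sample (may be empty).
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return `tumor_calls` with an `origin` column ("somatic"/"germline").
#' @export
classify_origin <- function(tumor_calls, normal_calls, min_overlap = 0.5) {
  n <- nrow(tumor_calls)
  origin <- rep("somatic", n)
  if (n > 0 && !is.null(normal_calls) && nrow(normal_calls) > 0) {
    for (i in seq_len(n)) {
      same <- normal_calls$chrom == tumor_calls$chrom[i]
      if (!any(same)) next
      nc <- normal_calls[same, , drop = FALSE]
      inter <- pmax(0, pmin(tumor_calls$end[i], nc$end) -
                      pmax(tumor_calls$start[i], nc$start))
      w_t <- tumor_calls$end[i] - tumor_calls$start[i]
      w_n <- nc$end - nc$start
      if (any(inter / w_t >= min_overlap & inter / w_n >= min_overlap)) {
        origin[i] <- "germline"
      }
    }
  }
  tumor_calls$origin <- origin
  tumor_calls
}

#' Write CNV calls as a BED-like TSV
#'
#' Columns: chrom, start, end, type, score (CBAS), origin.
#'
#' @param calls Call data frame (with `type`; `origin` optional).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_calls_bed <- function(calls, path) {
  origin <- if ("origin" %in% names(calls)) calls$origin else rep(".", nrow(calls))
  df <- data.frame(chrom = calls$chrom, start = calls$start, end = calls$end,
                   type = calls$type, score = calls$cbas, origin = origin)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a call BED written by [write_calls_bed()]
#' @param path BED file path.
#' @return Data frame with `chrom`, `start`, `end`, `type`, `score`, `origin`.
#' @export
read_calls_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "type", "score", "origin")[seq_len(ncol(df))]
  df
}
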