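#' Does a call detect a truth region?
#'
#' A called interval detects a ground-truth region when their intersection
#' covers strictly more than `frac` of the *truth* region's length.
#' Intervals are 0-based half-open on the same chromosome.
#'
#' @param call_start,call_end Call interval in bp.
#' @param truth_start,truth_end Truth interval in bp.
#' @param frac Required covered fraction of the truth region (default 0.5,
#'   strict inequality).
#' @return Logical.
#' @export
overlap_match <- function(call_start, call_end, truth_start, truth_end,
                          frac = 0.5) {
  if (any(call_end <= call_start) || any(truth_end <= truth_start)) {
    stop("intervals must have positive length", call. = FALSE)
  }
  inter <- pmax(0, pmin(call_end, truth_end) - pmax(call_start, truth_start))
  inter / (truth_end - truth_start) > frac
}

# logical matrix: calls x truths, TRUE where the call detects the truth
match_matrix <- function(calls, truths, frac = 0.5) {
  m <- matrix(FALSE, nrow(calls), nrow(truths))
  if (nrow(calls) == 0 || nrow(truths) == 0) return(m)
  for (j in seq_len(nrow(truths))) {
    same <- calls$chrom == truths$chrom[j]
    if (any(same)) {
      m[same, j] <- overlap_match(calls$start[same], calls$end[same],
                                  truths$start[j], truths$end[j], frac)
    }
  }
  m
}

#' Sensitivity and false discovery rate of a call set
#'
#' Sensitivity is the number of truth regions detected (covered by more
#' than 50% by some call) divided by the number of truth regions. FDR is
#' the number of calls detecting no truth region divided by the number of
#' calls; with zero calls the FDR is defined as 0 (no false discoveries
#' were made). With zero truth regions sensitivity is `NA`.
#'
#' @param calls Data frame of calls (`chrom`, `start`, `end`).
#' @param truths Data frame of truth regions (`chrom`, `start`, `end`).
#' @param frac Overlap fraction for [overlap_match()].
#' @return Named list: `sensitivity`, `fdr`, `n_truth`, `n_called`,
#'   `n_tp` (truths detected), `n_fp` (calls matching nothing).
#' @export
sensitivity_fdr <- function(calls, truths, frac = 0.5) {
  m <- match_matrix(calls, truths, frac)
  n_tp <- if (nrow(truths)) sum(apply(m, 2, any)) else 0L
  n_fp <- if (nrow(calls)) sum(!apply(m, 1, any)) else 0L
  list(
    sensitivity = if (nrow(truths) == 0) NA_real_ else n_tp / nrow(truths),
    fdr = if (nrow(calls) == 0) 0 else n_fp / nrow(calls),
    n_truth = nrow(truths), n_called = nrow(calls),
    n_tp = n_tp, n_fp = n_fp
  )
}

#' Precision, recall and F1 of a call set
#'
#' Recall equals sensitivity (detected truths over all truths); precision
#' is the fraction of calls that detect some truth region; F1 is their
#' harmonic mean. Undefined ratios (0/0) are `NA`.
#'
#' @inheritParams sensitivity_fdr
#' @return Named list: `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(calls, truths, frac = 0.5) {
  s <- sensitivity_fdr(calls, truths, frac)
  precision <- if (s$n_called == 0) NA_real_ else 1 - s$fdr
  recall <- s$sensitivity
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Overlapping density score between callers
#'
#' When no ground truth exists, concordance between callers is summarised
#' by \eqn{ODS = O_m \cdot O_r} where \eqn{O_m} is the mean number of a
#' method's events overlapped by each other method and
#' \eqn{O_r = O_m / NPE} with NPE the method's total predicted events.
#'
#' @param noe_pairwise Numeric vector of per-other-method overlap counts
#'   (or a single pre-averaged value).
#' @param npe Total number of events predicted by the method (> 0).
#' @return Named list: `o_m`, `o_r`, `ods`.
#' @examples
#' ods_score(10, 20)  # o_r = 0.5, ods = 5
#' @export
ods_score <- function(noe_pairwise, npe) {
  if (npe <= 0) stop("'npe' must be positive", call. = FALSE)
  o_m <- mean(noe_pairwise)
  o_r <- o_m / npe
  list(o_m = o_m, o_r = o_r, ods = o_m * o_r)
}

#' Evaluate a call set against ground truth
#'
#' Full report: overall sensitivity/FDR/precision/recall/F1, a per-length
#' breakdown over the standard region length levels, and a per-type
#' (gain/loss) breakdown. In the per-length table truths are stratified by
#' their own length (snapped to the nearest level) and calls by theirs, so
#' each level's FDR reflects calls of that size. In the per-type table a
#' truth counts as detected only by a call of the same type.
#'
#' @inheritParams sensitivity_fdr
#' @param length_levels Length levels in bp used for stratification.
#' @return An object of class `cbcnv_eval`: list with `overall` (counts and
#'   the five fractions), `by_length` (data frame), `by_type` (data frame).
#' @export
evaluate_calls <- function(calls, truths, frac = 0.5,
                           length_levels = c(2e3, 6e3, 1e4, 3e4, 5e4, 1e5)) {
  s <- sensitivity_fdr(calls, truths, frac)
  p <- precision_recall_f1(calls, truths, frac)
  overall <- c(s, p)

  snap <- function(len) {
    length_levels[max.col(-abs(outer(len, length_levels, "-")), "first")]
  }
  by_length <- do.call(rbind, lapply(length_levels, function(lv) {
    tr <- if (nrow(truths)) {
      truths[snap(truths$end - truths$start) == lv, , drop = FALSE]
    } else truths
    cl <- if (nrow(calls)) {
      calls[snap(calls$end - calls$start) == lv, , drop = FALSE]
    } else calls
    sens <- sensitivity_fdr(cl, tr, frac)$sensitivity
    fdr <- sensitivity_fdr(cl, truths, frac)$fdr  # level calls vs all truths
    data.frame(length = lv, n_truth = nrow(tr), n_called = nrow(cl),
               sensitivity = sens, fdr = fdr)
  }))

  by_type <- do.call(rbind, lapply(c("gain", "loss"), function(tp) {
    tr <- truths[truths$type == tp, , drop = FALSE]
    cl <- if ("type" %in% names(calls)) {
      calls[calls$type == tp, , drop = FALSE]
    } else {
      calls
    }
    st <- sensitivity_fdr(cl, tr, frac)
    data.frame(type = tp, n_truth = st$n_truth, n_called = st$n_called,
               sensitivity = st$sensitivity, fdr = st$fdr)
  }))

  out <- list(overall = overall, by_length = by_length, by_type = by_type)
  class(out) <- "cbcnv_eval"
  out
}

#' @export
print.cbcnv_eval <- function(x, ...) {
  o <- x$overall
  cat(sprintf("CNV call evaluation: %d calls vs %d truth regions\n",
              o$n_called, o$n_truth))
  cat(sprintf("  sensitivity %.3f  FDR %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
              o$sensitivity, o$fdr, o$precision, o$recall, o$f1))
  cat("  by length (bp):\n")
  print(x$by_length, row.names = FALSE)
  invisible(x)
}
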