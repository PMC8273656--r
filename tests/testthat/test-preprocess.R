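make_profile <- function(depth, gc = rep(0.5, length(depth)),
                         n_masked = rep(FALSE, length(depth)),
                         bin_size = 100) {
  starts <- (seq_along(depth) - 1) * bin_size
  out <- data.frame(chrom = "chrT", start = starts, end = starts + bin_size,
                    depth = depth, gc = gc, n_masked = n_masked,
                    stringsAsFactors = FALSE)
  attr(out, "bin_size") <- bin_size
  class(out) <- c("cbcnv_profile", "data.frame")
  out
}

test_that("binning masks N bins, drops the trailing short bin, and averages", {
  # 10,001 bp reference: 5 complete 2,000 bp bins, 1 bp dropped;
  # bin 3 sits inside an N gap
  ref <- paste(c(rep("A", 4000), rep("N", 2000), rep("G", 4001)), collapse = "")
  counts <- data.frame(chrom = "chrT", pos = 1:10001, count = 3)
  prof <- bin_and_mask(counts, reference = ref, bin_size = 2000)
  expect_equal(nrow(prof), 5L)
  expect_equal(prof$n_masked, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(prof$depth, rep(3, 5))           # uniform counts -> depth c
  expect_equal(prof$gc[1], 0)                   # all-A bin
  expect_equal(prof$gc[4], 1)                   # all-G bin
  # positions beyond the reference are rejected
  bad <- data.frame(chrom = "chrT", pos = 1:10002, count = 1)
  expect_error(bin_and_mask(bad, reference = ref, bin_size = 2000), "beyond")
})

test_that("per-bin count dialect uses counts as depth with supplied GC", {
  counts <- data.frame(chrom = "chrT", bin_start = c(0, 2000, 4000),
                       bin_end = c(2000, 4000, 6000), count = c(10, 20, 30))
  prof <- bin_and_mask(counts, bin_size = 2000, gc = c(0.4, 0.5, 0.6))
  expect_equal(prof$depth, c(10, 20, 30))
  expect_false(any(prof$n_masked))
  expect_error(bin_and_mask(counts, bin_size = 1000, gc = rep(0.5, 3)),
               "bin_size")
})

test_that("GC correction equalises stratum means and preserves the global mean", {
  # uniform GC: correction is the identity
  p <- make_profile(c(5, 7, 9, 11))
  expect_equal(gc_correct(p)$depth, p$depth)

  # direct substitution: RD=10, RD_m=20, RD_gc=10 -> 20
  p2 <- make_profile(c(10, 10, 30, 30), gc = c(0.3, 0.3, 0.6, 0.6))
  expect_equal(gc_correct(p2)$depth[1], 20)

  # two strata with means 8 and 12, global mean 10 -> both stratum means 10
  p3 <- make_profile(c(7, 9, 11, 13), gc = c(0.35, 0.35, 0.55, 0.55))
  out <- gc_correct(p3)
  expect_equal(mean(out$depth[1:2]), 10)
  expect_equal(mean(out$depth[3:4]), 10)
  expect_equal(mean(out$depth), mean(p3$depth))

  # masked bins are excluded from the statistics and left untouched
  p4 <- make_profile(c(100, 8, 12, 8, 12), gc = c(0.3, rep(0.5, 4)),
                     n_masked = c(TRUE, rep(FALSE, 4)))
  out4 <- gc_correct(p4)
  expect_equal(out4$depth[1], 100)
  expect_equal(mean(out4$depth[-1]), 10)

  # a zero-depth stratum cannot be rescaled: bins masked with a warning
  p5 <- make_profile(c(0, 0, 10, 10), gc = c(0.3, 0.3, 0.5, 0.5))
  expect_warning(out5 <- gc_correct(p5), "zero-depth")
  expect_true(all(out5$n_masked[1:2]))
})

test_that("random GC profiles: every stratum mean equals the global mean", {
  set.seed(41)
  for (rep in 1:5) {
    n <- 300
    p <- make_profile(rpois(n, 50) + 1, gc = round(runif(n, 0.3, 0.6), 2))
    out <- gc_correct(p)
    strata <- split(out$depth, round(out$gc, 2))
    for (s in strata) expect_equal(mean(s), mean(p$depth), tolerance = 1e-12)
  }
})

test_that("fused-lasso limits: identity at lambda 0, global mean at large lambda", {
  y <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(tv_denoise(y, 0), y)
  big <- tv_denoise(y, 1e9)
  expect_equal(big, rep(mean(y), length(y)))
  expect_error(tv_denoise(y, -1), ">= 0")
})

test_that("fused-lasso objective matches the dual-QP oracle on random signals", {
  set.seed(17)
  for (rep in 1:8) {
    n <- sample(30:120, 1)
    y <- cumsum(sample(c(0, 0, 0, 3, -3), n, TRUE)) + rnorm(n)
    lam <- runif(1, 0.2, 4)
    fit <- tv_denoise(y, lam)
    oracle <- tv_dual_oracle(y, lam)
    expect_lt(abs(tv_objective(y, fit, lam) - tv_objective(y, oracle, lam)),
              1e-8)
  }
})

test_that("optimal objective is below any hand-made segmentation's", {
  set.seed(23)
  y <- rnorm(60) + rep(c(0, 4, 0), each = 20)
  lam <- 2
  fit_obj <- tv_objective(y, tv_denoise(y, lam), lam)
  # hand segmentations: true blocks, one block, arbitrary split
  for (cuts in list(c(20, 40), integer(0), c(10, 30, 50))) {
    grp <- cut(seq_along(y), breaks = c(0, cuts, 60))
    beta <- stats::ave(y, grp)
    expect_lte(fit_obj, tv_objective(y, beta, lam) + 1e-10)
  }
})

test_that("noiseless piecewise-constant signals are recovered with exact breakpoints", {
  y <- rep(c(10, 50, 10, 80), times = c(30, 20, 30, 20))
  seg <- denoise_and_segment(make_profile(y), lambda = 1)
  expect_equal(nrow(seg), 4L)
  expect_equal(seg$first_bin, c(1L, 31L, 51L, 81L))
  expect_equal(seg$n_bins, c(30L, 20L, 30L, 20L))
  # fitted levels equal block means up to TV shrinkage lambda/len
  expect_equal(seg$value, c(10, 50, 10, 80), tolerance = 0.2)
})

test_that("segments partition the unmasked bins and RDS_m conventions differ as documented", {
  set.seed(31)
  y <- rnorm(100, 50, 3)
  mask <- rep(FALSE, 100); mask[40:45] <- TRUE
  p <- make_profile(y, n_masked = mask)
  seg <- denoise_and_segment(p, lambda = 5)
  expect_equal(sum(seg$n_bins), sum(!mask))
  expect_equal(seg$first_bin[1], 1L)
  expect_equal(seg$last_bin[nrow(seg)], sum(!mask))
  expect_true(all(seg$first_bin[-1] == seg$last_bin[-nrow(seg)] + 1L))
  # bin-weighted RDS_m equals the mean of the fitted bin values
  expect_equal(attr(seg, "rds_m"), mean(attr(seg, "fitted")))
  seg2 <- denoise_and_segment(p, lambda = 5, rds_m_weighting = "segment")
  expect_equal(attr(seg2, "rds_m"), mean(seg2$value))
})
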