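seg_fixture <- function(values, n_bins = rep(2L, length(values))) {
  last <- cumsum(n_bins)
  first <- last - n_bins + 1L
  starts <- (first - 1L) * 1000
  seg <- data.frame(chrom = "chrT", start = starts, end = last * 1000,
                    first_bin = first, last_bin = last, n_bins = n_bins,
                    value = values, stringsAsFactors = FALSE)
  attr(seg, "rds_m") <- sum(values * n_bins) / sum(n_bins)
  attr(seg, "bin_size") <- 1000
  class(seg) <- c("cbcnv_segments", "data.frame")
  seg
}

test_that("the upper fence is Q3 + w * IQR under linear-interpolation quartiles", {
  f <- tukey_threshold(c(1, 1, 3, 3), w = 1.5)
  expect_equal(f$q1, 1); expect_equal(f$q3, 3); expect_equal(f$T, 6)
  # constant scores: IQR 0, T = c, nothing strictly exceeds it
  fc <- tukey_threshold(rep(2.5, 10), w = 1.5)
  expect_equal(fc$T, 2.5)
  # 1..8 under type-7 interpolation: Q1 = 2.75, Q3 = 6.25, T = 11.5
  f8 <- tukey_threshold(1:8, w = 1.5)
  expect_equal(f8$q1, 2.75); expect_equal(f8$q3, 6.25); expect_equal(f8$T, 11.5)
  expect_error(tukey_threshold(1:3), "at least 4")
  expect_error(tukey_threshold(1:8, w = -1), ">= 0")
})

test_that("calls are exactly the segments above T, with adjacent runs merged", {
  seg <- seg_fixture(c(10, 10, 30, 30, 30, 10, 10, 50))
  scores <- c(0, 0, 5, 6, 5, 0, 0, 9)
  fence <- list(T = 4)
  calls <- call_cnvs(seg, scores, fence)
  expect_equal(nrow(calls), 2L)                      # merged run + singleton
  expect_equal(calls$first_seg, c(3L, 8L))
  expect_equal(calls$last_seg, c(5L, 8L))
  expect_equal(calls$start[1], seg$start[3])
  expect_equal(calls$end[1], seg$end[5])
  expect_equal(calls$cbas, c(6, 9))                  # max of members
  # merging changes intervals, never the flagged segment membership
  unmerged <- call_cnvs(seg, scores, fence, merge = FALSE)
  expect_equal(sort(unmerged$first_seg), which(scores > fence$T))
  # ties and sub-threshold scores produce nothing
  expect_equal(nrow(call_cnvs(seg, rep(4, 8), fence)), 0L)
  # single exceedance -> single-segment call
  one <- call_cnvs(seg, c(0, 0, 0, 5, 0, 0, 0, 0), fence)
  expect_equal(nrow(one), 1L)
  expect_equal(one$first_seg, 4L)
})

test_that("increasing w never increases the number of calls", {
  set.seed(47)
  scores <- c(rexp(40, 2), 5, 8, 12)
  seg <- seg_fixture(runif(43, 5, 50))
  n_prev <- Inf
  for (w in c(0, 0.5, 1, 1.5, 2, 3, 5)) {
    f <- tukey_threshold(scores, w = w)
    n <- nrow(call_cnvs(seg, scores, f))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("gain/loss typing compares call depth to the uncalled baseline", {
  seg <- seg_fixture(c(10, 12, 40, 11, 9), n_bins = c(2L, 2L, 2L, 2L, 2L))
  calls <- call_cnvs(seg, c(0, 0, 5, 0, 0), list(T = 1))
  typed <- assign_gain_loss(calls, seg)
  expect_equal(attr(typed, "baseline"), mean(c(10, 12, 11, 9)))
  expect_equal(typed$type, "gain")
  # a zero-depth call against a positive baseline is a loss
  seg2 <- seg_fixture(c(10, 12, 0, 11, 9))
  typed2 <- assign_gain_loss(call_cnvs(seg2, c(0, 0, 5, 0, 0), list(T = 1)), seg2)
  expect_equal(typed2$type, "loss")
  # a call exactly at the baseline ties to gain
  seg3 <- seg_fixture(c(10, 10, 10, 10, 10))
  typed3 <- assign_gain_loss(call_cnvs(seg3, c(0, 5, 0, 0, 0), list(T = 1)), seg3)
  expect_equal(typed3$type, "gain")
  # whole profile called: no baseline exists
  expect_error(assign_gain_loss(call_cnvs(seg, rep(5, 5), list(T = 1)), seg),
               "baseline")
})

test_that("origin classification uses 50% reciprocal overlap with normal calls", {
  tum <- data.frame(chrom = "chrT", start = c(0, 5000, 9000),
                    end = c(1000, 6000, 10000),
                    cbas = 1, type = "gain", stringsAsFactors = FALSE)
  nor <- data.frame(chrom = "chrT", start = c(0, 5600), end = c(1000, 7100),
                    stringsAsFactors = FALSE)
  out <- classify_origin(tum, nor)
  expect_equal(out$origin[1], "germline")   # identical interval
  # call 2: overlap 400 of 1000 (40% reciprocal of the tumor call) -> somatic
  expect_equal(out$origin[2], "somatic")
  expect_equal(out$origin[3], "somatic")    # no overlapping normal call
  # empty normal call set: everything somatic
  out2 <- classify_origin(tum, tum[0, ])
  expect_true(all(out2$origin == "somatic"))
})

test_that("call BED output round-trips", {
  dir <- withr::local_tempdir()
  calls <- data.frame(chrom = "chrT", start = c(0, 8000), end = c(4000, 9000),
                      cbas = c(2.5, 7), type = c("gain", "loss"),
                      origin = c("somatic", "germline"),
                      stringsAsFactors = FALSE)
  p <- write_calls_bed(calls, file.path(dir, "calls.bed"))
  back <- read_calls_bed(p)
  expect_equal(back$start, calls$start)
  expect_equal(back$type, calls$type)
  expect_equal(back$score, calls$cbas)
  expect_equal(back$origin, calls$origin)
})
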