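mb <- 1e6

test_that("flat profiles yield a single segment", {
  y <- rep(0, 80)
  seg <- segment_arm(y, start = (0:79) * mb, end = (1:80) * mb)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_bins, 80L)
})

test_that("a clean step is recovered at the exact bin", {
  set.seed(1)
  y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.01)
  seg <- segment_arm(y, (0:99) * mb, (1:100) * mb)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$n_bins, c(50L, 50L))
  expect_equal(seg$mean, c(0, 1), tolerance = 0.02)
})

test_that("single-bin arms return a flagged trivial segment", {
  seg <- segment_arm(0.3, 0, mb)
  expect_true(isTRUE(attr(seg, "trivial")))
  expect_equal(nrow(seg), 1L)
})

test_that("segmentation equals the O(n^2) optimal-partitioning oracle", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    k <- sample(0:3, 1)
    cps <- sort(sample(1:(n - 1), min(k, n - 1)))
    means <- cumsum(c(0, runif(length(cps), -1.5, 1.5)))
    lvl <- rep(means, diff(c(0, cps, n)))
    y <- lvl + rnorm(n, 0, 0.15)
    seg <- segment_arm(y, (0:(n - 1)) * mb, (1:n) * mb)
    got <- cumsum(seg$n_bins)
    want <- dp_segment_oracle(y, oracle_penalty(y))
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("merging follows smallest-gap-first up to the threshold", {
  p <- lga_params()
  two <- data.frame(chrom = "c", arm = "p", start = c(0, 10) * mb,
                    end = c(10, 20) * mb, mean = c(0.00, 0.05),
                    n_bins = c(10L, 10L))
  m <- merge_segments(two, p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$mean, 0.025)  # equal-weight average

  apart <- data.frame(chrom = "c", arm = "p", start = c(0, 10, 20) * mb,
                      end = c(10, 20, 30) * mb, mean = c(0.0, 0.5, 0.0),
                      n_bins = rep(10L, 3))
  expect_equal(merge_segments(apart, p)$mean, c(0.0, 0.5, 0.0))

  # chain merge under smallest-gap-first with leftmost tie-break:
  # gaps (0.06, 0.06) -> merge left pair -> (0.03[20], 0.12[10]),
  # gap 0.09 < 0.10 -> merge -> weighted mean 0.06
  chain <- data.frame(chrom = "c", arm = "p", start = c(0, 10, 20) * mb,
                      end = c(10, 20, 30) * mb, mean = c(0.00, 0.06, 0.12),
                      n_bins = rep(10L, 3))
  m <- merge_segments(chain, p)
  expect_equal(nrow(m), 1L)
  expect_equal(m$mean, 0.06)
})

test_that("sub-min_seg_bins fragments are absorbed into the closer flank", {
  p <- lga_params()
  frag <- data.frame(chrom = "c", arm = "p",
                     start = c(0, 12, 13) * mb, end = c(12, 13, 30) * mb,
                     mean = c(0.0, 0.45, 0.6), n_bins = c(12L, 1L, 17L))
  m <- merge_segments(frag, p)
  expect_equal(nrow(m), 2L)
  # fragment joined the 0.6 flank (closer mean), flank boundary moved left
  expect_equal(m$start[2], 12 * mb)
  expect_equal(m$mean[1], 0.0)
})

test_that("count_lga applies both flank-length and step rules per arm", {
  p <- lga_params()
  seg <- function(chrom, arm, start, end, mean)
    data.frame(chrom = chrom, arm = arm, start = start * mb, end = end * mb,
               mean = mean, n_bins = 10L)
  expect_equal(count_lga(rbind(seg("c", "p", 0, 12, 0),
                               seg("c", "p", 12, 27, 0.4)), p), 1L)
  expect_equal(count_lga(rbind(seg("c", "p", 0, 8, 0),
                               seg("c", "p", 8, 23, 0.4)), p), 0L)
  # both flanks >= 10 Mb and a 0.5 step, but across the centromere
  expect_equal(count_lga(rbind(seg("c", "p", 0, 12, 0),
                               seg("c", "q", 12, 27, 0.5)), p), 0L)
  # sub-delta step
  expect_equal(count_lga(rbind(seg("c", "p", 0, 12, 0),
                               seg("c", "p", 12, 27, 0.2)), p), 0L)
})

test_that("LGA count is invariant to a global ratio shift", {
  set.seed(7)
  s <- simulate_and_score(7, base_window = 50e3, windows = 50e3)
  segs <- s$result$segments[["50000"]]
  p <- lga_params()
  shifted <- segs
  shifted$mean <- shifted$mean + 1.23
  expect_equal(count_lga(shifted, p), count_lga(segs, p))
})

test_that("raising delta never increases the LGA count", {
  set.seed(8)
  s <- simulate_and_score(8, base_window = 50e3, windows = 50e3)
  segs <- s$result$segments[["50000"]]
  deltas <- c(0.15, 0.25, 0.4, 0.6, 1.0)
  counts <- vapply(deltas, function(d)
    count_lga(segs, lga_params(delta = d, merge_threshold = 0.10)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("model integration takes the rounded median and propagates ND", {
  r <- integrate_models(c(`5000` = 21, `25000` = 22, `50000` = 20,
                          `1e+05` = 21, `5e+05` = 19, `1e+06` = 21))
  expect_equal(r$gia, 21L)   # median of (19,20,21,21,21,22)
  expect_equal(r$status, "OK")

  expect_equal(integrate_models(c(a = 7, b = 7, c = 7))$gia, 7L)
  expect_equal(integrate_models(c(a = 10, b = 11))$gia, 11L)  # half rounds up

  nd <- integrate_models(c(a = 10, b = NA), qc = c(TRUE, FALSE))
  expect_equal(nd$status, "ND")
  expect_true(is.na(nd$gia))
  expect_error(integrate_models(integer(0)), "no window models")
})
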