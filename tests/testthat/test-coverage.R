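tiny_genome <- genome_model(data.frame(chrom = "c1", arm = "p",
                                       start = 0, end = 4e6))
tiny_grid <- build_grid(tiny_genome, 1e6)
tiny_bins <- function(counts, gc = rep(0.5, length(counts))) {
  data.frame(chrom = tiny_grid$chrom, start = tiny_grid$start,
             end = tiny_grid$end, count = counts, gc = gc)
}

test_that("flat counts normalize to all-zero log2 ratios", {
  prof <- normalize_counts(tiny_bins(c(100L, 100L, 100L, 100L)), tiny_grid)
  expect_true(all(prof$data$log2_ratio == 0))
})

test_that("median normalization matches the hand-computed log2(c/median)", {
  prof <- normalize_counts(tiny_bins(c(10L, 10L, 10L, 20L)), tiny_grid,
                           gc_correct = FALSE)
  # median count is 10, so ratios are log2(c/10)
  expect_equal(prof$data$log2_ratio, log2(c(10, 10, 10, 20) / 10))
  expect_lt(abs(median(prof$data$log2_ratio[prof$data$retained])), 1e-9)
})

test_that("zero-count and out-of-range-GC bins are masked with reasons", {
  prof <- normalize_counts(tiny_bins(c(10L, 0L, 10L, 10L),
                                     gc = c(0.5, 0.5, 0.9, 0.5)),
                           tiny_grid, gc_correct = FALSE)
  expect_equal(prof$data$reason, c("", "zero_count", "gc_out_of_range", ""))
  expect_equal(prof$data$retained, c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(is.na(prof$data$log2_ratio[!prof$data$retained])))
  expect_true(all(is.finite(prof$data$log2_ratio[prof$data$retained])))
})

test_that("grid mismatches and excess filtering are hard errors", {
  bins <- tiny_bins(rep(10L, 4))
  bins$start[2] <- bins$start[2] + 1
  expect_error(normalize_counts(bins, tiny_grid), "offending bin")
  expect_error(normalize_counts(tiny_bins(rep(10L, 3)), tiny_grid), "rows")
  expect_error(normalize_counts(tiny_bins(c(0L, 0L, 0L, 10L)), tiny_grid),
               "fails QC")
  neg <- tiny_bins(c(10L, -1L, 10L, 10L))
  expect_error(normalize_counts(neg, tiny_grid), "non-negative")
})

test_that("log2 ratios are invariant to global count scaling", {
  g <- reduced_genome()
  grid <- build_grid(g, 1e6)
  set.seed(42)
  counts <- rnbinom(nrow(grid), mu = 500, size = 50) + 1L
  gc <- pmin(pmax(rnorm(nrow(grid), 0.5, 0.06), 0.3), 0.7)
  mk <- function(k) data.frame(chrom = grid$chrom, start = grid$start,
                               end = grid$end, count = counts * k, gc = gc)
  p1 <- normalize_counts(mk(1L), grid)
  p7 <- normalize_counts(mk(7L), grid)
  expect_equal(p1$data$log2_ratio, p7$data$log2_ratio, tolerance = 1e-12)
})

test_that("GC correction is near-idempotent on GC-independent counts", {
  g <- reduced_genome()
  grid <- build_grid(g, 250e3)
  set.seed(43)
  counts <- rnbinom(nrow(grid), mu = 2000, size = 100) + 1L
  gc <- pmin(pmax(rnorm(nrow(grid), 0.5, 0.06), 0.3), 0.7)
  bins <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                     count = counts, gc = gc)
  on <- normalize_counts(bins, grid, gc_correct = TRUE)
  off <- normalize_counts(bins, grid, gc_correct = FALSE)
  expect_lt(mean(abs(on$data$log2_ratio - off$data$log2_ratio),
                 na.rm = TRUE), 0.01)
})

test_that("rebinning nests fine bins exactly into coarser windows", {
  g <- reduced_genome()
  cfg <- sim_config(seed = 12)
  tp <- simulate_truth_profile(g, 3, seed = 12, config = cfg)
  fine <- simulate_bin_counts(tp, g, 25e3, cfg)
  coarse <- rebin_counts(fine, g, 100e3)
  grid <- build_grid(g, 100e3)
  expect_equal(nrow(coarse), nrow(grid))
  expect_equal(coarse$start, grid$start)
  expect_equal(sum(coarse$count), sum(fine$count))  # counts conserved
  expect_true(all(coarse$gc >= 0.3 & coarse$gc <= 0.7))
})
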