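g <- reduced_genome()

test_that("zero-alteration truth profiles are flat diploid", {
  tp <- simulate_truth_profile(g, 0, seed = 1)
  expect_equal(tp$true_lga_count, 0L)
  expect_true(all(tp$segments$ratio == 1.0))
  expect_equal(nrow(tp$segments), nrow(g))  # one segment per arm
})

test_that("truth recount closure: brute-force scan reproduces the target", {
  for (seed in 1:20) {
    target <- local({set.seed(seed); sample(0:30, 1)})
    tp <- simulate_truth_profile(g, target, seed = seed)
    recount <- lga_count_from_segments(tp$segments, tp$min_lga_len,
                                       tp$delta_truth, "linear")
    expect_identical(recount, target)
    # segments tile each arm exactly
    for (a in seq_len(nrow(g))) {
      s <- tp$segments[tp$segments$chrom == g$chrom[a] &
                         tp$segments$arm == g$arm[a], ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], g$start[a])
      expect_equal(s$end[nrow(s)], g$end[a])
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    }
  }
})

test_that("unachievable LGA targets raise a capacity error", {
  expect_error(simulate_truth_profile(g, 1000, seed = 1), "budget")
})

test_that("truth profiles are deterministic given the seed", {
  a <- simulate_truth_profile(g, 8, seed = 7)
  b <- simulate_truth_profile(g, 8, seed = 7)
  expect_identical(a, b)
  c <- simulate_truth_profile(g, 8, seed = 8)
  expect_false(identical(a$segments, c$segments))
})

test_that("zero purity erases all copy-number signal from counts", {
  cfg <- sim_config(seed = 5, gc_bias_amplitude = 0)
  tp <- simulate_truth_profile(g, 10, seed = 5, purity = 0, config = cfg)
  bins <- simulate_bin_counts(tp, g, 100e3, cfg)
  # per-truth-segment count means should all match the neutral expectation
  mid <- (bins$start + bins$end) / 2
  seg_of <- integer(nrow(bins))
  for (i in seq_len(nrow(tp$segments)))
    seg_of[bins$chrom == tp$segments$chrom[i] &
             mid >= tp$segments$start[i] & mid < tp$segments$end[i]] <- i
  full <- bins$end - bins$start == 100e3
  m <- tapply(bins$count[full], tp$segments$ratio[seg_of[full]], mean)
  expect_lt(max(m) / min(m), 1.03)  # flat across copy states
})

test_that("mean count over a flat arm matches coverage * window", {
  cfg <- sim_config(seed = 6, gc_bias_amplitude = 0, dispersion = 1e9)
  tp <- simulate_truth_profile(g, 0, seed = 6, purity = 0.5, config = cfg)
  w <- 25e3
  bins <- simulate_bin_counts(tp, g, w, cfg)
  full <- bins$end - bins$start == w
  mu <- tp$coverage * w
  se <- sqrt(mu / sum(full))  # Poisson limit at huge dispersion
  expect_lt(abs(mean(bins$count[full]) - mu), 3 * se)
})

test_that("bin count simulation is byte-identical under one seed", {
  cfg <- sim_config(seed = 9)
  tp <- simulate_truth_profile(g, 5, seed = 9, config = cfg)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_bin_tsv(simulate_bin_counts(tp, g, 50e3, cfg), f1)
  write_bin_tsv(simulate_bin_counts(tp, g, 50e3, cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  file.remove(f1, f2)
})

test_that("bin simulation rejects out-of-contract windows", {
  cfg <- sim_config(seed = 1)
  tp <- simulate_truth_profile(g, 0, seed = 1, config = cfg)
  expect_error(simulate_bin_counts(tp, g, 1000, cfg), "window_bp")
  expect_error(simulate_bin_counts(tp, g, 2e6, cfg), "window_bp")
})

test_that("cohort simulation honours censoring, bands and class means", {
  cfg0 <- sim_config(seed = 10, censor_fraction = 0)
  co <- simulate_cohort(50, cfg0)
  expect_true(all(co$pfs_event == 1))
  expect_true(all(co$os_event == 1))
  expect_true(all(co$ref_score[co$hrd_class == "HRD"] >= 56))
  expect_true(all(co$ref_score[co$hrd_class == "HRN"] <= 42))
  expect_true(all(co$ref_score[co$hrd_class == "HRM"] %in% 43:55))
  expect_true(all(co$os_days >= co$pfs_days))

  cfg <- sim_config(seed = 11, censor_fraction = 0,
                    group_mean_pfs_days = c(HRD = 2850, HRM = 1200, HRN = 620),
                    class_probs = c(HRD = 1/3, HRM = 1/3, HRN = 1/3))
  big <- simulate_cohort(2000, cfg)
  m <- tapply(big$pfs_days, big$hrd_class, mean)
  nc <- table(big$hrd_class)
  # exponential mean has relative SE 1/sqrt(n); allow 3 standard errors
  expect_lt(abs(m[["HRD"]] / 2850 - 1), 3 / sqrt(nc[["HRD"]]))
  expect_lt(abs(m[["HRM"]] / 1200 - 1), 3 / sqrt(nc[["HRM"]]))
  expect_lt(abs(m[["HRN"]] / 620 - 1), 3 / sqrt(nc[["HRN"]]))
})

test_that("degenerate cohorts are flagged, tiny ones rejected", {
  expect_error(simulate_cohort(1, sim_config(seed = 1)), ">= 2")
  cfg <- sim_config(seed = 2, class_probs = c(HRD = 1, HRM = 0, HRN = 0))
  expect_warning(simulate_cohort(5, cfg), "all-one-class")
})
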