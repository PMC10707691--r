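#' Simulate a ground-truth copy-number profile
#'
#' Draws a piecewise-constant tumor copy-ratio profile on a genome-arm grid
#' with a known number of LGAs (large-scale genomic alterations). Every LGA
#' breakpoint separates two same-arm segments that are both at least
#' `min_lga_len` long and whose copy ratios differ by at least `delta_truth`
#' (linear ratio scale). Additional short (< `min_lga_len`) "distractor"
#' segments may be inserted; their breakpoints never count as LGAs because
#' one flank is short, and they are placed so that missing them downstream
#' cannot create a spurious LGA.
#'
#' Copy ratios are drawn from the level set \{0.5, 1.0, 1.6, 2.4\} (relative
#' to the diploid baseline), so that after dilution by the lowest studied
#' purity (0.4) every truth step still exceeds the pipeline's detection
#' threshold.
#'
#' @param genome a [genome_model()].
#' @param n_lga_target requested true LGA count (>= 0).
#' @param seed integer seed; identical inputs + seed give identical profiles.
#' @param purity tumor cell fraction in \[0,1\]; drawn from
#'   `config$purity_range` when `NULL`.
#' @param coverage effective coverage (reads-per-bp equivalent); drawn from
#'   `config$coverage_range` when `NULL`.
#' @param config a [sim_config()] supplying ranges and constants.
#' @return A `truth_profile`: list with `segments` (data.frame `chrom`,
#'   `arm`, `start`, `end`, `ratio`), `true_lga_count`, `purity`, `coverage`,
#'   `min_lga_len`, `delta_truth`, `seed`.
#' @examples
#' tp <- simulate_truth_profile(reduced_genome(), n_lga_target = 8, seed = 7)
#' tp$true_lga_count
#' @export
simulate_truth_profile <- function(genome, n_lga_target, seed,
                                   purity = NULL, coverage = NULL,
                                   config = sim_config(seed)) {
  stopifnot(inherits(genome, "genome_model"), n_lga_target >= 0)
  min_len <- 10e6
  delta_truth <- 0.5
  levels <- c(0.5, 1.0, 1.6, 2.4)
  lens <- arm_lengths(genome)
  capacity <- pmax(floor(lens / min_len) - 1L, 0L)
  if (n_lga_target > sum(capacity))
    stop("n_lga_target = ", n_lga_target, " exceeds the genome's LGA budget (",
         sum(capacity), " = sum over arms of floor(arm_length/",
         format(min_len, scientific = FALSE), ") - 1)")

  with_seed(seed, {
    if (!is.null(purity)) {
      if (purity < 0 || purity > 1) stop("purity must be in [0, 1]")
    } else purity <- runif(1, config$purity_range[1], config$purity_range[2])
    if (is.null(coverage))
      coverage <- runif(1, config$coverage_range[1], config$coverage_range[2])

    # spread breakpoints over arms, respecting per-arm capacity
    k_arm <- integer(nrow(genome))
    remaining <- capacity
    for (i in seq_len(n_lga_target)) {
      open <- which(k_arm < remaining)
      pick <- if (length(open) == 1L) open else sample(open, 1L)
      k_arm[pick] <- k_arm[pick] + 1L
    }

    seg_list <- vector("list", nrow(genome))
    for (a in seq_len(nrow(genome))) {
      L <- genome$end[a] - genome$start[a]
      k <- k_arm[a]
      if (k == 0L) {
        lvl <- 1.0
        segs <- data.frame(start = genome$start[a], end = genome$end[a],
                           ratio = lvl)
      } else {
        # k+1 segment lengths, each >= min_len, summing to L
        slack <- L - (k + 1L) * min_len
        cuts <- sort(runif(k, 0, slack))
        extra <- diff(c(0, cuts, slack))
        seg_len <- min_len + extra
        # level random walk: consecutive segments always on distinct levels
        lvl <- numeric(k + 1L)
        lvl[1] <- sample(levels, 1L)
        for (j in 2L:(k + 1L))
          lvl[j] <- sample(setdiff(levels, lvl[j - 1L]), 1L)
        ends <- genome$start[a] + cumsum(seg_len)
        segs <- data.frame(start = c(genome$start[a], ends[-(k + 1L)]),
                           end = ends, ratio = lvl)
        segs$end[k + 1L] <- genome$end[a]  # guard rounding
      }
      segs$chrom <- genome$chrom[a]
      segs$arm <- genome$arm[a]

      # distractor: a short segment splitting one long segment into
      # same-level flanks (its breakpoints are never LGAs, and losing it
      # downstream merges identical levels, never creating one)
      if (n_lga_target > 0L && runif(1) < 0.3) {
        short <- runif(1, 3e6, 8e6)
        ok <- which(segs$end - segs$start >= 2 * min_len + short)
        if (length(ok) > 0L) {
          i <- if (length(ok) == 1L) ok else sample(ok, 1L)
          s0 <- segs$start[i]; e0 <- segs$end[i]; r0 <- segs$ratio[i]
          left <- runif(1, min_len, (e0 - s0) - short - min_len)
          ins <- data.frame(start = c(s0, s0 + left, s0 + left + short),
                            end = c(s0 + left, s0 + left + short, e0),
                            ratio = c(r0, sample(setdiff(levels, r0), 1L), r0),
                            chrom = segs$chrom[i], arm = segs$arm[i])
          segs <- rbind(segs[seq_len(i - 1L), ], ins,
                        segs[seq_len(nrow(segs)) > i, ])
        }
      }
      seg_list[[a]] <- segs
    }
    segments <- do.call(rbind, seg_list)
    segments <- segments[, c("chrom", "arm", "start", "end", "ratio")]
    rownames(segments) <- NULL

    recount <- lga_count_from_segments(segments, min_len, delta_truth,
                                       ratio_scale = "linear")
    if (recount != n_lga_target)  # internal consistency guard
      stop("internal error: generated profile recounts to ", recount,
           " LGAs, not ", n_lga_target)
    structure(list(segments = segments, true_lga_count = as.integer(recount),
                   purity = purity, coverage = coverage,
                   min_lga_len = min_len, delta_truth = delta_truth,
                   seed = as.integer(seed)),
              class = "truth_profile")
  })
}

#' Count LGAs from an explicit segment table
#'
#' Brute-force scan of adjacent same-arm segment pairs: a pair counts when
#' both segments are at least `min_len` long and the step between their
#' values is at least `delta`. Arm (centromere) boundaries never contribute.
#' Works on either linear copy ratios or log2 ratios; for `"linear"` the
#' step is the absolute difference of ratios, for `"log2"` of log2 ratios.
#'
#' @param segments data.frame with `chrom`, `arm`, `start`, `end` and a
#'   value column (`ratio` for linear, `mean` for log2).
#' @param min_len minimum flank length (bp).
#' @param delta minimum step.
#' @param ratio_scale `"linear"` or `"log2"`.
#' @return integer LGA count.
#' @export
lga_count_from_segments <- function(segments, min_len = 10e6, delta = 0.5,
                                    ratio_scale = c("linear", "log2")) {
  ratio_scale <- match.arg(ratio_scale)
  val <- if (ratio_scale == "linear") segments$ratio else segments$mean
  key <- paste(segments$chrom, segments$arm)
  n_lga <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(segments$start[idx])]
    if (length(idx) < 2L) next
    len <- segments$end[idx] - segments$start[idx]
    v <- val[idx]
    for (j in seq_len(length(idx) - 1L)) {
      if (len[j] >= min_len && len[j + 1L] >= min_len &&
          abs(v[j + 1L] - v[j]) >= delta)
        n_lga <- n_lga + 1L
    }
  }
  n_lga
}

# smooth unimodal GC bias multiplier over gc in [0.3, 0.7]: 1 at the edges,
# 1 + amplitude at gc = 0.5
gc_bias_curve <- function(gc, amplitude) {
  1 + amplitude * pmax(0, 1 - ((gc - 0.5) / 0.2)^2)
}

#' Simulate binned sWGS read counts from a truth profile
#'
#' Tiles the genome at `window_bp`, assigns each bin a GC fraction
#' (short-range variation around 0.5, clamped to \[0.30, 0.70\], independent
#' of the copy-number state as in real genomes), and draws
#' negative-binomial counts with mean
#' `coverage * width * (purity * ratio + (1 - purity)) * gc_bias(gc)`:
#' the tumor signal diluted by normal-cell admixture, modulated by a smooth
#' GC bias, with overdispersion `config$dispersion` (variance
#' `mu + mu^2/dispersion`).
#'
#' @param profile a `truth_profile` from [simulate_truth_profile()].
#' @param genome the [genome_model()] the profile was simulated on.
#' @param window_bp bin width in bp, within \[5000, 1e6\].
#' @param config a [sim_config()]; `config$seed` makes the draw
#'   deterministic.
#' @return data.frame with columns `chrom`, `start`, `end`, `count`, `gc`
#'   (the bin-table interchange format).
#' @examples
#' cfg <- sim_config(seed = 2)
#' tp <- simulate_truth_profile(reduced_genome(), 4, seed = 2, config = cfg)
#' bins <- simulate_bin_counts(tp, reduced_genome(), 50000, cfg)
#' head(bins)
#' @export
simulate_bin_counts <- function(profile, genome, window_bp, config) {
  stopifnot(inherits(profile, "truth_profile"),
            inherits(genome, "genome_model"), inherits(config, "sim_config"))
  if (window_bp < 5000 || window_bp > 1e6)
    stop("window_bp must lie in [5000, 1000000]")
  if (window_bp > min(arm_lengths(genome)))
    stop("window_bp is larger than the smallest arm (",
         min(arm_lengths(genome)), " bp)")
  if (profile$purity < 0 || profile$purity > 1)
    stop("purity must be in [0, 1]")

  grid <- build_grid(genome, window_bp)
  mid <- (grid$start + grid$end) / 2

  with_seed(config$seed, {
    # per-bin GC fraction: short-range variation independent of copy state
    # (real bin GC fluctuates at sub-Mb scale, not at segment scale)
    gc <- pmin(pmax(rnorm(nrow(grid), 0.5, 0.06), 0.30), 0.70)

    # true ratio of the segment each bin midpoint falls in
    ratio <- rep(NA_real_, nrow(grid))
    segs <- profile$segments
    skey <- paste(segs$chrom, segs$arm)
    gkey <- paste(grid$chrom, grid$arm)
    for (k in unique(skey)) {
      si <- which(skey == k)
      gi <- which(gkey == k)
      if (length(gi) == 0L) next
      pos <- findInterval(mid[gi], segs$start[si], rightmost.closed = TRUE)
      pos[pos < 1L] <- 1L
      ratio[gi] <- segs$ratio[si][pos]
    }
    if (anyNA(ratio)) stop("profile segments do not tile the genome")

    mu <- profile$coverage * (grid$end - grid$start) *
      (profile$purity * ratio + (1 - profile$purity)) *
      gc_bias_curve(gc, config$gc_bias_amplitude)
    count <- rnbinom(length(mu), mu = mu, size = config$dispersion)
    data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
               count = as.integer(count), gc = round(gc, 4),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a clinical cohort with HRD classes and survival times
#'
#' Draws per-patient HRD class, GIA score, a reference (Myriad-style) score
#' consistent with the class's band (HRN <= 42, HRM 43-55, HRD >= 56), and
#' exponential PFS/OS times with class-specific means; records are censored
#' with probability `config$censor_fraction`.
#'
#' @param n cohort size (>= 2).
#' @param config a [sim_config()].
#' @return data.frame: `sample_id`, `hrd_class`, `gia`, `ref_score`,
#'   `pfs_days`, `pfs_event`, `os_days`, `os_event`.
#' @examples
#' co <- simulate_cohort(20, sim_config(seed = 3))
#' table(co$hrd_class)
#' @export
simulate_cohort <- function(n, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (n < 2) stop("cohort size must be >= 2")
  with_seed(config$seed, {
    cls <- sample(names(config$class_probs), n, replace = TRUE,
                  prob = config$class_probs)
    if (length(unique(cls)) == 1L)
      warning("all-one-class cohort: group comparisons downstream ",
              "(log-rank) will be undefined")
    gia <- integer(n); ref <- integer(n)
    for (i in seq_len(n)) {
      gia[i] <- switch(cls[i],
                       HRD = sample(20:32, 1L),
                       HRM = sample(15:19, 1L),
                       HRN = sample(0:14, 1L))
      # HRN draws avoid exactly 42, where the published band edge (<= 42
      # negative) and positivity cutoff (>= 42) overlap; no study sample
      # sits there either
      ref[i] <- switch(cls[i],
                       HRD = sample(56:100, 1L),
                       HRM = sample(43:55, 1L),
                       HRN = sample(0:41, 1L))
    }
    pfs <- rexp(n, rate = 1 / config$group_mean_pfs_days[cls])
    os <- pfs + rexp(n, rate = 1 / pmax(
      config$group_mean_os_days[cls] - config$group_mean_pfs_days[cls], 100))
    pfs_event <- rbinom(n, 1L, 1 - config$censor_fraction)
    os_event <- rbinom(n, 1L, 1 - config$censor_fraction)
    data.frame(sample_id = sprintf("S%03d", seq_len(n)),
               hrd_class = cls, gia = gia, ref_score = ref,
               pfs_days = round(pfs, 1), pfs_event = pfs_event,
               os_days = round(os, 1), os_event = os_event,
               stringsAsFactors = FALSE)
  })
}
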