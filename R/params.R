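#' LGA counting and segmentation parameters
#'
#' Tunable constants of the LGA/GIA pipeline. An LGA (large-scale genomic
#' alteration) is a breakpoint between two adjacent segments on the same
#' chromosome arm, both at least `min_lga_len` long, whose mean log2 copy
#' ratios differ by at least `delta`.
#'
#' @param min_lga_len minimum flank length in bp for a breakpoint to count as
#'   an LGA. Default 10 Mb, the defining scale of "large-scale" alterations.
#' @param delta minimum absolute log2-ratio step at a counted breakpoint.
#'   Default 0.25 (a one-copy gain at ~40% purity in a diploid background).
#' @param merge_threshold adjacent segments whose means differ by less than
#'   this are merged before counting. Default 0.10. Must be < `delta`.
#' @param penalty_scale multiplier of the segmentation penalty
#'   `beta = penalty_scale * sigma^2 * log(n)`, where `sigma` is the
#'   per-bin noise scale (MAD of successive differences / sqrt(2)).
#'   Default 3.0.
#' @param min_seg_bins segments with fewer bins than this are absorbed into
#'   the adjacent segment with the closer mean before threshold merging.
#'   Default 3. This removes the "transition bin" artifact: the single bin
#'   straddling a true breakpoint takes an intermediate mean and would
#'   otherwise sit between the two large flanks, hiding their adjacency from
#'   the LGA count.
#' @return A list of class `lga_params`.
#' @examples
#' lga_params()
#' lga_params(delta = 0.3)
#' @export
lga_params <- function(min_lga_len = 10e6, delta = 0.25,
                       merge_threshold = 0.10, penalty_scale = 3.0,
                       min_seg_bins = 3L) {
  stopifnot(min_lga_len > 0, delta > 0, penalty_scale > 0, min_seg_bins >= 1)
  if (!(merge_threshold > 0 && merge_threshold < delta))
    stop("merge_threshold must satisfy 0 < merge_threshold < delta")
  structure(list(min_lga_len = min_lga_len, delta = delta,
                 merge_threshold = merge_threshold,
                 penalty_scale = penalty_scale,
                 min_seg_bins = as.integer(min_seg_bins)),
            class = "lga_params")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic sWGS / cohort generator. Defaults
#' describe the study conditions the package emulates: FFPE tumor shallow WGS
#' at 0.4-0.8x effective coverage, purity 0.4-0.9, overdispersed
#' (negative-binomial) counts, a smooth unimodal GC bias, and a cohort whose
#' mean progression-free survival decreases from the HRD class to the HRN
#' class.
#'
#' @param seed integer seed; every simulator call is deterministic given it.
#' @param n_samples cohort size (default 20).
#' @param lga_target_range inclusive integer range the per-sample true LGA
#'   count is drawn from.
#' @param purity_range tumor purity range (fraction of tumor cells).
#' @param coverage_range effective coverage range in reads-per-bp equivalent
#'   (expected count of a neutral bin = coverage * bin width).
#' @param dispersion negative-binomial size parameter; counts have variance
#'   `mu + mu^2/dispersion`. Default 100 (per-bin log2 noise ~0.15, typical
#'   of FFPE sWGS bins).
#' @param gc_bias_amplitude relative height of the unimodal GC bias bump over
#'   gc in \[0.3, 0.7\]. Default 0.3; 0 disables the bias.
#' @param censor_fraction probability a survival record is censored.
#' @param group_mean_pfs_days named mean PFS (days) per HRD class; defaults
#'   (2893, 1217, 631) are 95.04 / 39.97 / 20.73 months at 30.4375 d/month.
#' @param group_mean_os_days named mean OS (days) per HRD class.
#' @param class_probs cohort allocation over classes HRD/HRM/HRN.
#' @param window_bp base bin width (bp) at which counts are simulated.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$group_mean_pfs_days
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 20L,
                       lga_target_range = c(0L, 30L),
                       purity_range = c(0.4, 0.9),
                       coverage_range = c(0.4, 0.8),
                       dispersion = 100,
                       gc_bias_amplitude = 0.3,
                       censor_fraction = 0.2,
                       group_mean_pfs_days = c(HRD = 2893, HRM = 1217, HRN = 631),
                       group_mean_os_days = c(HRD = 3200, HRM = 1500, HRN = 800),
                       class_probs = c(HRD = 0.65, HRM = 0.20, HRN = 0.15),
                       window_bp = 5000L) {
  stopifnot(length(lga_target_range) == 2L,
            lga_target_range[1] <= lga_target_range[2],
            length(purity_range) == 2L, purity_range[1] <= purity_range[2],
            purity_range[1] >= 0, purity_range[2] <= 1,
            length(coverage_range) == 2L,
            coverage_range[1] <= coverage_range[2], coverage_range[1] > 0,
            dispersion > 0, gc_bias_amplitude >= 0,
            censor_fraction >= 0, censor_fraction < 1,
            all(c("HRD", "HRM", "HRN") %in% names(group_mean_pfs_days)),
            all(class_probs >= 0), sum(class_probs) > 0)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 lga_target_range = as.integer(lga_target_range),
                 purity_range = purity_range, coverage_range = coverage_range,
                 dispersion = dispersion,
                 gc_bias_amplitude = gc_bias_amplitude,
                 censor_fraction = censor_fraction,
                 group_mean_pfs_days = group_mean_pfs_days,
                 group_mean_os_days = group_mean_os_days,
                 class_probs = class_probs[c("HRD", "HRM", "HRN")],
                 window_bp = as.integer(window_bp)),
            class = "sim_config")
}

# evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards (expr is evaluated lazily, after seeding)
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
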