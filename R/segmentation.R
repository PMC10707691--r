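#' Segment one arm's log2-ratio profile
#'
#' Exact change-point search on the per-bin log2 ratios of a single
#' chromosome arm: the returned partition attains the global minimum of
#' `sum of per-segment squared deviations + beta * (#segments - 1)` with
#' `beta = penalty_scale * sigma^2 * log(n)` and
#' `sigma = MAD(successive differences) / sqrt(2)` (Gaussian-scaled). The
#' search is PELT, which is exact for this penalized least-squares cost, in
#' compiled code; results are deterministic.
#'
#' @param ratios per-bin log2 ratios of the retained bins, in genomic order.
#' @param start,end genomic coordinates of those bins (bp).
#' @param params [lga_params()].
#' @return data.frame: `start`, `end`, `mean`, `n_bins`, one row per
#'   segment. With fewer than 2 bins a single trivial segment is returned,
#'   flagged by `attr(, "trivial")`.
#' @examples
#' y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.05)
#' segment_arm(y, start = 0:99 * 1e6, end = 1:100 * 1e6)
#' @export
segment_arm <- function(ratios, start, end, params = lga_params()) {
  n <- length(ratios)
  stopifnot(length(start) == n, length(end) == n)
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  if (n < 2) {
    seg <- data.frame(start = if (n) start[1] else numeric(0),
                      end = if (n) end[n] else numeric(0),
                      mean = if (n) ratios[1] else numeric(0),
                      n_bins = if (n) 1L else integer(0))
    attr(seg, "trivial") <- TRUE
    return(seg)
  }
  beta <- segment_penalty(ratios, params)
  ends_idx <- .pelt_changepoints(ratios, beta)
  starts_idx <- c(1L, ends_idx[-length(ends_idx)] + 1L)
  data.frame(
    start = start[starts_idx],
    end = end[ends_idx],
    mean = vapply(seq_along(ends_idx), function(i)
      mean(ratios[starts_idx[i]:ends_idx[i]]), numeric(1)),
    n_bins = ends_idx - starts_idx + 1L)
}

# penalty beta for one arm; floored at a tiny positive value so noiseless
# profiles resolve to the fewest segments rather than one per bin
segment_penalty <- function(ratios, params) {
  sigma <- mad(diff(ratios)) / sqrt(2)
  beta <- params$penalty_scale * sigma^2 * log(length(ratios))
  if (!is.finite(beta) || beta <= 0) beta <- 1e-12
  beta
}

#' Segment every arm of a coverage profile
#'
#' Applies [segment_arm()] to the retained bins of each arm, then
#' [merge_segments()].
#'
#' @param profile a `coverage_profile` from [normalize_counts()].
#' @param params [lga_params()].
#' @return A `segment_set` data.frame: `chrom`, `arm`, `start`, `end`,
#'   `mean`, `n_bins`.
#' @export
segment_profile <- function(profile, params = lga_params()) {
  stopifnot(inherits(profile, "coverage_profile"))
  d <- profile$data[profile$data$retained, , drop = FALSE]
  key <- paste(d$chrom, d$arm)
  out <- lapply(unique(key), function(k) {
    di <- d[key == k, , drop = FALSE]
    seg <- segment_arm(di$log2_ratio, di$start, di$end, params)
    if (nrow(seg) == 0L) return(NULL)
    seg$chrom <- di$chrom[1]
    seg$arm <- di$arm[1]
    seg
  })
  segs <- do.call(rbind, out)
  segs <- segs[, c("chrom", "arm", "start", "end", "mean", "n_bins")]
  rownames(segs) <- NULL
  merge_segments(segs, params)
}

#' Merge near-equal adjacent segments
#'
#' Two passes per arm. First, segments with fewer than `params$min_seg_bins`
#' bins are absorbed into the adjacent segment whose mean is closer (these
#' are almost always the single bins straddling a breakpoint, whose
#' intermediate mean would otherwise separate the two large flanks).
#' Second, the adjacent pair with the smallest absolute mean difference is
#' merged repeatedly while that difference is below
#' `params$merge_threshold` (leftmost pair on ties). Merged means are
#' bin-count-weighted averages. On return no adjacent same-arm pair differs
#' by less than the threshold.
#'
#' @param segs segment data.frame (`chrom`, `arm`, `start`, `end`, `mean`,
#'   `n_bins`).
#' @param params [lga_params()].
#' @return The merged segment data.frame.
#' @export
merge_segments <- function(segs, params = lga_params()) {
  key <- paste(segs$chrom, segs$arm)
  out <- lapply(unique(key), function(k) {
    s <- segs[key == k, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    # absorb transition fragments into the closer-mean neighbor
    while (nrow(s) > 1L && any(s$n_bins < params$min_seg_bins)) {
      i <- which(s$n_bins < params$min_seg_bins)[1]
      nb <- if (i == 1L) 2L
      else if (i == nrow(s)) i - 1L
      else if (abs(s$mean[i - 1L] - s$mean[i]) <=
                 abs(s$mean[i + 1L] - s$mean[i])) i - 1L
      else i + 1L
      j <- min(i, nb)
      w <- s$n_bins[c(j, j + 1L)]
      s$mean[j] <- sum(s$mean[c(j, j + 1L)] * w) / sum(w)
      s$end[j] <- s$end[j + 1L]
      s$n_bins[j] <- sum(w)
      s <- s[-(j + 1L), , drop = FALSE]
    }
    while (nrow(s) > 1L) {
      gaps <- abs(diff(s$mean))
      i <- which.min(gaps)           # which.min takes the leftmost tie
      if (gaps[i] >= params$merge_threshold) break
      w <- s$n_bins[c(i, i + 1L)]
      s$mean[i] <- sum(s$mean[c(i, i + 1L)] * w) / sum(w)
      s$end[i] <- s$end[i + 1L]
      s$n_bins[i] <- sum(w)
      s <- s[-(i + 1L), , drop = FALSE]
    }
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count large-scale genomic alterations (LGAs)
#'
#' An LGA is a breakpoint between two adjacent segments of the same
#' chromosome arm where both segments span at least `params$min_lga_len` and
#' the absolute difference of their mean log2 ratios is at least
#' `params$delta`. Arm boundaries (centromeres) never contribute.
#'
#' @param segs merged `segment_set` data.frame.
#' @param params [lga_params()].
#' @return integer LGA count.
#' @examples
#' segs <- data.frame(chrom = "sim1", arm = "p",
#'                    start = c(0, 12e6), end = c(12e6, 27e6),
#'                    mean = c(0, 0.4), n_bins = c(12L, 15L))
#' count_lga(segs)  # 1
#' @export
count_lga <- function(segs, params = lga_params()) {
  key <- paste(segs$chrom, segs$arm)
  total <- 0L
  for (k in unique(key)) {
    s <- segs[key == k, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) < 2L) next
    len <- s$end - s$start
    long <- len >= params$min_lga_len
    step <- abs(diff(s$mean)) >= params$delta
    total <- total + sum(long[-nrow(s)] & long[-1L] & step)
  }
  as.integer(total)
}

#' Integrate per-window LGA counts into the GIA score
#'
#' The genomic instability assessment (GIA) is the median of the LGA counts
#' across window models, with half-integers rounded up. If any model failed
#' QC the sample is undetermined (status `"ND"`) and no score is emitted.
#'
#' @param per_model_lga named integer vector (names = window sizes in bp).
#' @param qc logical vector, TRUE where the model passed QC (default all).
#' @return A `gia_result`: list with `per_model_lga`, `gia` (NA when ND) and
#'   `status` (`"OK"` or `"ND"`).
#' @examples
#' integrate_models(c(`5000` = 21, `10000` = 22, `50000` = 20,
#'                    `1e+05` = 21, `5e+05` = 19, `1e+06` = 21))$gia  # 21
#' @export
integrate_models <- function(per_model_lga,
                             qc = rep(TRUE, length(per_model_lga))) {
  if (length(per_model_lga) == 0L) stop("no window models supplied")
  stopifnot(length(qc) == length(per_model_lga))
  if (any(!qc)) {
    return(structure(list(per_model_lga = per_model_lga, gia = NA_integer_,
                          status = "ND"), class = "gia_result"))
  }
  m <- median(as.numeric(per_model_lga))
  structure(list(per_model_lga = per_model_lga,
                 gia = as.integer(floor(m + 0.5)), status = "OK"),
            class = "gia_result")
}

#' @export
print.gia_result <- function(x, ...) {
  cat("GIA result [", x$status, "]\n", sep = "")
  cat("  per-model LGA:",
      paste(names(x$per_model_lga), x$per_model_lga, sep = "=",
            collapse = " "), "\n")
  if (x$status == "OK") cat("  GIA =", x$gia, "\n")
  invisible(x)
}

#' Score one sample: bins to GIA
#'
#' Runs the full per-sample pipeline: for each window model the fine bin
#' table is aggregated onto that window grid ([rebin_counts()]), normalized
#' to log2 ratios ([normalize_counts()]), segmented and merged
#' ([segment_profile()]), and its LGAs counted ([count_lga()]); the counts
#' are then integrated into the GIA score ([integrate_models()]). A model
#' whose sample fails bin-level QC marks the whole sample undetermined (ND).
#'
#' @param bins fine bin table (`chrom`, `start`, `end`, `count`, `gc`).
#' @param genome the [genome_model()] the bins live on.
#' @param windows window model sizes in bp; default
#'   `c(5, 25, 50, 100, 500, 1000) * 1000` (six models spanning 5-1000 kb).
#' @param params [lga_params()].
#' @param gc_correct passed to [normalize_counts()].
#' @return A `gia_result` (see [integrate_models()]), with the per-model
#'   merged segments attached as `segments`.
#' @examples
#' cfg <- sim_config(seed = 11)
#' tp <- simulate_truth_profile(reduced_genome(), 6, seed = 11, config = cfg)
#' bins <- simulate_bin_counts(tp, reduced_genome(), 50000, cfg)
#' gia_score(bins, reduced_genome(), windows = c(50, 100, 500) * 1000)
#' @export
gia_score <- function(bins, genome,
                      windows = c(5, 25, 50, 100, 500, 1000) * 1000,
                      params = lga_params(), gc_correct = TRUE) {
  stopifnot(length(windows) >= 1)
  base_w <- max(bins$end - bins$start)
  counts <- setNames(integer(length(windows)), as.character(windows))
  qc <- setNames(rep(TRUE, length(windows)), as.character(windows))
  seg_out <- list()
  for (i in seq_along(windows)) {
    w <- windows[i]
    if (w < base_w) stop("window ", w, " is finer than the input bins (",
                         base_w, " bp)")
    bw <- if (w == base_w) bins else rebin_counts(bins, genome, w)
    grid <- build_grid(genome, w)
    prof <- tryCatch(normalize_counts(bw, grid, gc_correct),
                     error = function(e) NULL)
    if (is.null(prof)) {
      qc[i] <- FALSE
      counts[i] <- NA_integer_
      next
    }
    segs <- segment_profile(prof, params)
    seg_out[[as.character(w)]] <- segs
    counts[i] <- count_lga(segs, params)
  }
  res <- integrate_models(counts, qc)
  res$segments <- seg_out
  res
}
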