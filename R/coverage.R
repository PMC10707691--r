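#' Tile a genome into fixed-width bins
#'
#' Each chromosome arm is tiled left-to-right with non-overlapping windows of
#' `window_bp`; the last bin of an arm may be short, and no bin ever crosses
#' an arm (centromere) boundary.
#'
#' @param genome a [genome_model()].
#' @param window_bp bin width in bp (>= 1000).
#' @return A `bin_grid` data.frame: `chrom`, `arm`, `start`, `end`, sorted by
#'   (chrom, start); `ceiling(arm_length / window_bp)` bins per arm.
#' @examples
#' build_grid(reduced_genome(), 1e6)[1:3, ]
#' @export
build_grid <- function(genome, window_bp) {
  stopifnot(inherits(genome, "genome_model"))
  if (window_bp <= 0) stop("window_bp must be positive")
  if (window_bp < 1000) stop("window_bp must be >= 1000")
  out <- vector("list", nrow(genome))
  for (a in seq_len(nrow(genome))) {
    starts <- seq(genome$start[a], genome$end[a] - 1, by = window_bp)
    out[[a]] <- data.frame(chrom = genome$chrom[a], arm = genome$arm[a],
                           start = starts,
                           end = pmin(starts + window_bp, genome$end[a]),
                           stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, out)
  grid <- grid[order(match(grid$chrom, unique(genome$chrom)), grid$start), ]
  rownames(grid) <- NULL
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

#' Aggregate a fine bin table onto a coarser window grid
#'
#' Sums counts of fine bins falling into each coarse bin (coarse windows are
#' tiled from the arm start, so when `window_bp` is a multiple of the fine
#' width the fine bins nest exactly); GC is the width-weighted mean.
#'
#' @param bins bin table (`chrom`, `start`, `end`, `count`, `gc`).
#' @param genome the [genome_model()] the bins were tiled on.
#' @param window_bp target window width (bp).
#' @return A coarser bin table in the same format.
#' @export
rebin_counts <- function(bins, genome, window_bp) {
  arm <- assign_arms(bins, genome)
  astart <- genome$start[arm]
  idx <- floor((bins$start - astart) / window_bp)
  key <- paste(bins$chrom, genome$arm[arm], idx)
  width <- bins$end - bins$start
  first <- !duplicated(key)
  out <- data.frame(
    chrom = bins$chrom[first],
    start = (astart + idx * window_bp)[first],
    end = pmin(astart + (idx + 1) * window_bp, genome$end[arm])[first],
    count = as.integer(tapply(bins$count, key, sum)[key[first]]),
    gc = as.numeric(tapply(bins$gc * width, key, sum)[key[first]] /
                      tapply(width, key, sum)[key[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# index of the genome arm containing each bin; errors on orphan bins
assign_arms <- function(bins, genome) {
  arm <- rep(NA_integer_, nrow(bins))
  for (a in seq_len(nrow(genome))) {
    hit <- bins$chrom == genome$chrom[a] &
      bins$start >= genome$start[a] & bins$end <= genome$end[a]
    arm[hit] <- a
  }
  if (anyNA(arm)) {
    i <- which(is.na(arm))[1]
    stop("bin not contained in any genome arm: ", bins$chrom[i], ":",
         bins$start[i], "-", bins$end[i])
  }
  arm
}

#' Normalize binned read counts to log2 copy ratios
#'
#' Filters uninformative bins (zero count, or GC outside \[0.28, 0.72\]),
#' optionally corrects GC bias by dividing each count by the median count of
#' its GC decile (deciles computed over retained bins; the correction is
#' applied only when the retained GC values span enough dynamic range —
#' interquartile range >= 0.05 with >= 500 bins — for decile medians to be
#' informative), and converts to
#' median-centred log2 ratios: `log2(count_corrected)` minus its median over
#' retained bins, so the median retained log2 ratio is exactly 0 (for an odd
#' number of bins this equals `log2(count / median(count))`).
#'
#' A sample losing more than half of its bins fails QC with an error: such
#' samples are reported as undetermined (ND) by the scoring pipeline rather
#' than given a score.
#'
#' @param bins bin table (`chrom`, `start`, `end`, `count`, `gc`).
#' @param grid the [build_grid()] the table is expected to match.
#' @param gc_correct apply GC decile-median correction (default TRUE).
#' @return A `coverage_profile`: list with `grid`, and `data` holding per bin
#'   `chrom`, `arm`, `start`, `end`, `gc`, `count`, `log2_ratio` (NA where
#'   filtered), `retained`, `reason` (`""`, `"zero_count"` or
#'   `"gc_out_of_range"`).
#' @examples
#' g <- reduced_genome()
#' grid <- build_grid(g, 1e6)
#' bins <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
#'                    count = 100L, gc = 0.5)
#' prof <- normalize_counts(bins, grid)
#' all(prof$data$log2_ratio == 0)
#' @export
normalize_counts <- function(bins, grid, gc_correct = TRUE) {
  stopifnot(inherits(grid, "bin_grid"))
  if (nrow(bins) != nrow(grid))
    stop("bin table has ", nrow(bins), " rows but grid has ", nrow(grid))
  mism <- which(bins$chrom != grid$chrom | bins$start != grid$start |
                  bins$end != grid$end)
  if (length(mism) > 0) {
    i <- mism[1]
    stop("bin table does not match grid; first offending bin: ",
         bins$chrom[i], ":", bins$start[i], "-", bins$end[i])
  }
  if (any(bins$count < 0)) stop("counts must be non-negative")

  reason <- rep("", nrow(bins))
  reason[bins$gc < 0.28 | bins$gc > 0.72] <- "gc_out_of_range"
  reason[bins$count == 0] <- "zero_count"
  retained <- reason == ""
  frac_filtered <- mean(!retained)
  if (frac_filtered > 0.5)
    stop("sample fails QC: ", round(100 * frac_filtered), "% of bins filtered")

  corrected <- as.numeric(bins$count)
  # decile medians are only informative when the GC values actually spread
  # over a range where the bias can vary and each decile holds enough bins;
  # otherwise the "correction" just injects decile-sampling noise (the GC
  # effect over a narrow range is below count noise)
  gc_informative <- sum(retained) >= 500 &&
    diff(quantile(bins$gc[retained], c(0.25, 0.75))) >= 0.05
  if (gc_correct && gc_informative) {
    br <- unique(quantile(bins$gc[retained], probs = 0:10 / 10))
    if (length(br) > 2) {
      dec <- cut(bins$gc, breaks = br, include.lowest = TRUE)
      med <- tapply(corrected[retained], dec[retained], median)
      med[!is.finite(med) | med == 0] <- NA
      f <- as.numeric(med[as.character(dec)])
      f[is.na(f)] <- 1
      corrected <- corrected / f
    }
  }
  l2 <- rep(NA_real_, nrow(bins))
  l2[retained] <- log2(corrected[retained])
  l2[retained] <- l2[retained] - median(l2[retained])

  structure(list(
    grid = grid,
    data = data.frame(chrom = grid$chrom, arm = grid$arm, start = grid$start,
                      end = grid$end, gc = bins$gc, count = bins$count,
                      log2_ratio = l2, retained = retained, reason = reason,
                      stringsAsFactors = FALSE),
    frac_filtered = frac_filtered,
    gc_corrected = isTRUE(gc_correct)),
    class = "coverage_profile")
}
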