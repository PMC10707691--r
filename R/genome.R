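#' Genome models: chromosome-arm tables
#'
#' A genome model is a data frame with one row per chromosome arm and columns
#' `chrom`, `arm` (`"p"` or `"q"`), `start`, `end` (0-based half-open
#' coordinates on the chromosome). Arms are the natural unit for copy-number
#' scoring because centromeres never contribute breakpoints.
#'
#' @param arms data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @return An object of class `genome_model` (a validated data.frame).
#' @examples
#' g <- reduced_genome()
#' sum(arm_lengths(g))  # ~600 Mb
#' @export
genome_model <- function(arms) {
  stopifnot(is.data.frame(arms),
            all(c("chrom", "arm", "start", "end") %in% names(arms)))
  arms <- arms[, c("chrom", "arm", "start", "end")]
  arms$chrom <- as.character(arms$chrom)
  arms$arm   <- as.character(arms$arm)
  arms$start <- as.numeric(arms$start)
  arms$end   <- as.numeric(arms$end)
  if (nrow(arms) == 0L) stop("genome model must contain at least one arm")
  if (any(arms$end <= arms$start)) stop("all arm lengths must be > 0")
  if (!all(arms$arm %in% c("p", "q"))) stop("arm must be 'p' or 'q'")
  # arms of one chromosome must not overlap
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1L && any(a$start[-1L] < a$end[-nrow(a)]))
      stop("overlapping arms on chromosome ", ch)
  }
  rownames(arms) <- NULL
  class(arms) <- c("genome_model", "data.frame")
  arms
}

#' @describeIn genome_model Reduced 6-chromosome, 12-arm, 600 Mb karyotype
#'   used by the simulator and test-suite (fast, same arm-scale structure as
#'   a real genome).
#' @export
reduced_genome <- function() {
  mb <- 1e6
  genome_model(data.frame(
    chrom = rep(paste0("sim", 1:6), each = 2),
    arm   = rep(c("p", "q"), 6),
    start = c(0, 50, 0, 45, 0, 40, 0, 50, 0, 40, 0, 35) * mb,
    end   = c(50, 110, 45, 105, 40, 100, 50, 100, 40, 95, 35, 90) * mb,
    stringsAsFactors = FALSE
  ))
}

#' @describeIn genome_model Full hg19 arm table (chr1-22, chrX; arms split at
#'   the UCSC gap-table centromeres), shipped as packaged data.
#' @export
hg19_genome <- function() {
  path <- system.file("extdata", "hg19_arms.tsv", package = "hrdgia",
                      mustWork = TRUE)
  genome_model(read.delim(path, stringsAsFactors = FALSE))
}

#' @describeIn genome_model Arm lengths in bp, named `chrom_arm`.
#' @param genome a `genome_model`.
#' @export
arm_lengths <- function(genome) {
  setNames(genome$end - genome$start, paste0(genome$chrom, "_", genome$arm))
}
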