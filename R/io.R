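#' Read and write the package's plain-text interchange formats
#'
#' Bin tables are BED-style TSVs with a header line and columns `chrom`,
#' `start`, `end`, `count`, `gc` (tab-separated, UTF-8, Unix newlines).
#' Truth profiles travel as JSON sidecars; cohorts as TSVs with the columns
#' produced by [simulate_cohort()].
#'
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @param bins bin table data.frame.
#' @export
write_bin_tsv <- function(bins, path) {
  stopifnot(all(c("chrom", "start", "end", "count", "gc") %in% names(bins)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("chrom", "start", "end", "count", "gc"),
                   collapse = "\t"), con, sep = "\n")
  writeLines(paste(bins$chrom, format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE),
                   bins$count, bins$gc, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' @rdname io
#' @export
read_bin_tsv <- function(path) {
  bins <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count", "gc")
  if (!all(need %in% names(bins)))
    stop("malformed bin TSV ", path, ": missing column(s) ",
         paste(setdiff(need, names(bins)), collapse = ", "))
  bad <- which(!is.finite(bins$count) | bins$count < 0 |
                 !is.finite(bins$start) | !is.finite(bins$end) |
                 bins$end <= bins$start)
  if (length(bad) > 0)
    stop("malformed bin TSV ", path, ": invalid record at line ",
         bad[1] + 1L)  # +1 for the header line
  bins[, need]
}

#' @rdname io
#' @param profile a `truth_profile`.
#' @export
write_truth_json <- function(profile, path) {
  stopifnot(inherits(profile, "truth_profile"))
  jsonlite::write_json(
    list(segments = profile$segments,
         true_lga_count = profile$true_lga_count,
         purity = profile$purity, coverage = profile$coverage,
         min_lga_len = profile$min_lga_len,
         delta_truth = profile$delta_truth, seed = profile$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(segments = as.data.frame(x$segments),
                 true_lga_count = as.integer(x$true_lga_count),
                 purity = x$purity, coverage = x$coverage,
                 min_lga_len = x$min_lga_len, delta_truth = x$delta_truth,
                 seed = as.integer(x$seed)),
            class = "truth_profile")
}

#' @rdname io
#' @param cohort cohort data.frame.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cohort_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Packaged validation cohort tables
#'
#' The 20-patient ovarian-cancer comparison cohort distributed with the
#' package as plain-text fixtures: per-sample academic HRD classes with
#' Myriad reference bands and scores, the 3x3 cross-stratification of the
#' two sWGS library chemistries ("R" rows vs "W" columns), and the two 2x2
#' stratifications of each chemistry against the Myriad classification
#' (rows = academic call, columns = Myriad call; order negative, positive).
#' Sample 17 is undetermined (`ND`) on the academic assay and is excluded
#' from contingency analyses.
#'
#' @return list with `cohort` (data.frame), `r_vs_w` (3x3 matrix),
#'   `r_vs_myriad`, `w_vs_myriad` (2x2 matrices).
#' @examples
#' tabs <- validation_tables()
#' cohens_kappa(tabs$r_vs_w)
#' @export
validation_tables <- function() {
  ext <- function(f) system.file("extdata", f, package = "hrdgia",
                                 mustWork = TRUE)
  cohort <- read.delim(ext("validation_cohort_scores.tsv"),
                       stringsAsFactors = FALSE)
  t3 <- read.delim(ext("validation_stratification_3x3.tsv"),
                   stringsAsFactors = FALSE)
  r_vs_w <- as.matrix(t3[, c("HRN", "HRM", "HRD")])
  dimnames(r_vs_w) <- list(t3$r_class, c("HRN", "HRM", "HRD"))
  t2 <- read.delim(ext("validation_stratification_2x2.tsv"),
                   stringsAsFactors = FALSE)
  m2 <- function(meth) {
    d <- t2[t2$method == meth, ]
    m <- as.matrix(d[, c("HRN", "HRD")])
    dimnames(m) <- list(d$row_class, c("HRN", "HRD"))
    m
  }
  list(cohort = cohort, r_vs_w = r_vs_w,
       r_vs_myriad = m2("R"), w_vs_myriad = m2("W"))
}
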