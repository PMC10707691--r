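#' Simulate a batch of samples to disk
#'
#' Generates `config$n_samples` truth profiles with LGA targets drawn from
#' `config$lga_target_range`, writes one bin TSV and one truth JSON per
#' sample plus the synthetic clinical cohort TSV, and a manifest of every
#' output with its MD5 checksum. Fully deterministic given `config$seed`.
#'
#' @param outdir output directory (created if missing).
#' @param config a [sim_config()].
#' @param genome a [genome_model()] (default [reduced_genome()]).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_simulate <- function(outdir, config = sim_config(),
                         genome = reduced_genome()) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir)
  files <- character(0)
  n <- config$n_samples
  if (n > 0) {
    targets <- with_seed(config$seed, {
      sample(config$lga_target_range[1]:config$lga_target_range[2],
             n, replace = TRUE)
    })
    for (i in seq_len(n)) {
      sid <- sprintf("sample_%03d", i)
      seed_i <- config$seed + 1000L + i
      cfg_i <- config
      cfg_i$seed <- seed_i
      tp <- simulate_truth_profile(genome, targets[i], seed = seed_i,
                                   config = cfg_i)
      bins <- simulate_bin_counts(tp, genome, config$window_bp, cfg_i)
      fb <- file.path(outdir, paste0(sid, ".bins.tsv"))
      ft <- file.path(outdir, paste0(sid, ".truth.json"))
      write_bin_tsv(bins, fb)
      write_truth_json(tp, ft)
      files <- c(files, fb, ft)
    }
    if (n >= 2) {  # cohort-level draws need at least two patients
      fc <- file.path(outdir, "cohort.tsv")
      write_cohort_tsv(simulate_cohort(n, config), fc)
      files <- c(files, fc)
    }
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(outdir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Score bin TSVs into GIA results and HRD classes
#'
#' Runs [gia_score()] on each input file. Malformed files yield an error
#' record (and the remaining files are still processed); QC failures yield
#' status `"ND"` with no score. Nothing is silently dropped.
#'
#' @param files character vector of bin TSV paths (>= 1).
#' @param genome a [genome_model()].
#' @param windows,params,gc_correct passed to [gia_score()].
#' @return data.frame: `sample_id`, `status` (`OK`/`ND`/`ERROR`), `gia`,
#'   `class3`, `class2`, `error` (message or `""`), plus one
#'   `lga_w<window>` column per model.
#' @export
run_score <- function(files, genome = reduced_genome(),
                      windows = c(5, 25, 50, 100, 500, 1000) * 1000,
                      params = lga_params(), gc_correct = TRUE) {
  if (length(files) < 1) stop("need at least one bin TSV")
  rows <- lapply(files, function(f) {
    sid <- sub("\\.bins\\.tsv$", "", basename(f))
    base <- data.frame(sample_id = sid, status = "ERROR", gia = NA_integer_,
                       class3 = NA_character_, class2 = NA_character_,
                       error = "", stringsAsFactors = FALSE)
    for (w in windows) base[[paste0("lga_w", w)]] <- NA_integer_
    tryCatch({
      bins <- read_bin_tsv(f)
      res <- gia_score(bins, genome, windows, params, gc_correct)
      base$status <- res$status
      base$gia <- res$gia
      base$class3 <- if (res$status == "OK") classify_three(res$gia) else NA
      base$class2 <- if (res$status == "OK") classify_two(res$gia) else NA
      for (w in windows)
        base[[paste0("lga_w", w)]] <- res$per_model_lga[[as.character(w)]]
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Method-concordance report: GIA calls vs a reference score
#'
#' Compares two-class academic HRD calls against reference positivity
#' (score >= 42) on a classified cohort: 2x2 contingency table (columns =
#' reference, order negative/positive), Cohen's kappa with interpretation,
#' PPA, Fisher's exact test, and Spearman correlation of the raw GIA against
#' the raw reference score. Undetermined (NA) samples are excluded and
#' counted in `n_excluded`.
#'
#' @param cohort data.frame with `gia` and `ref_score` (classes are derived
#'   with [classify_cohort()] if absent).
#' @return list with `table`, `kappa`, `ppa`, `fisher`, `spearman`,
#'   `n`, `n_excluded`.
#' @examples
#' co <- simulate_cohort(20, sim_config(seed = 4))
#' run_compare(co)$kappa
#' @export
run_compare <- function(cohort) {
  stopifnot(all(c("gia", "ref_score") %in% names(cohort)))
  cohort <- classify_cohort(cohort)
  ok <- !is.na(cohort$class2) & !is.na(cohort$ref_positive)
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    message(n_excluded, " undetermined sample(s) excluded from concordance")
  d <- cohort[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no overlapping determined samples to compare")
  t2 <- contingency_table(d$class2, ifelse(d$ref_positive, "HRD", "HRN"),
                          levels = c("HRN", "HRD"))
  list(table = t2,
       kappa = cohens_kappa(t2),
       ppa = ppa(t2),
       fisher = fisher_exact(t2),
       spearman = spearman_rho(d$gia, d$ref_score),
       n = nrow(d), n_excluded = n_excluded)
}

#' Cohort survival report
#'
#' Wrapper over [survival_by_class()]: per-class KM summaries always; the
#' log-rank test and Cox model only when more than one class is present
#' (single-group cohorts still get their KM tables, with a message).
#'
#' @param cohort cohort data.frame (see [simulate_cohort()]).
#' @param time_col,event_col survival columns (default PFS).
#' @return list as in [survival_by_class()].
#' @export
run_survival <- function(cohort, time_col = "pfs_days",
                         event_col = "pfs_event") {
  res <- survival_by_class(cohort, time_col, event_col)
  if (is.null(res$logrank))
    message("single class or no events: log-rank/Cox not computed; ",
            "KM tables still emitted")
  res
}
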