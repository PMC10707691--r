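#' HRD classification from the GIA score
#'
#' Three-class calling: HRN (negative) for GIA <= 14, HRM (mild) for
#' 15-19, HRD (deficient) for >= 20. Two-class calling collapses HRM into
#' HRD: positive iff GIA >= 15. `NA` scores (undetermined samples, ND)
#' propagate as `NA`.
#'
#' @param gia integer GIA score(s), >= 0 or NA.
#' @return character vector of classes (`"HRN"`, `"HRM"`, `"HRD"`, or NA).
#' @examples
#' classify_three(c(5, 14, 15, 19, 20, 25))
#' classify_two(c(14, 15, 16))
#' @export
classify_three <- function(gia) {
  gia <- as.numeric(gia)
  if (any(gia < 0, na.rm = TRUE)) stop("GIA scores must be >= 0")
  ifelse(is.na(gia), NA_character_,
         ifelse(gia <= 14, "HRN", ifelse(gia <= 19, "HRM", "HRD")))
}

#' @rdname classify_three
#' @export
classify_two <- function(gia) {
  cls3 <- classify_three(gia)
  ifelse(is.na(cls3), NA_character_, ifelse(cls3 == "HRN", "HRN", "HRD"))
}

#' Band a Myriad-style reference score
#'
#' Bands the 0-100 reference genomic-instability score: N for <= 42, M for
#' 43-55, D for >= 56. Clinical positivity uses the >= 42 cutoff; note that a
#' score of exactly 42 is banded N yet counts as positive — both facts are
#' reported rather than silently reconciled, matching how the banding and
#' positivity rules are published.
#'
#' @param score numeric reference score(s) in \[0, 100\].
#' @return data.frame with columns `score`, `band` (`"N"`, `"M"`, `"D"`) and
#'   `positive` (logical, `score >= 42`).
#' @examples
#' myriad_band(c(22, 41, 42, 50, 59))
#' @export
myriad_band <- function(score) {
  score <- as.numeric(score)
  if (any(score < 0 | score > 100, na.rm = TRUE))
    stop("reference scores must lie in [0, 100]")
  band <- ifelse(is.na(score), NA_character_,
                 ifelse(score <= 42, "N", ifelse(score < 56, "M", "D")))
  data.frame(score = score, band = band,
             positive = ifelse(is.na(score), NA, score >= 42))
}

#' Classify a cohort table
#'
#' Adds three-class, two-class and reference-band columns to a cohort data
#' frame holding `gia` and (optionally) `ref_score`.
#'
#' @param cohort data.frame with at least `sample_id` and `gia`.
#' @return The input with `class3`, `class2` and (when `ref_score` is
#'   present) `ref_band`, `ref_positive` columns appended.
#' @export
classify_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort), "gia" %in% names(cohort))
  cohort$class3 <- classify_three(cohort$gia)
  cohort$class2 <- classify_two(cohort$gia)
  if ("ref_score" %in% names(cohort)) {
    mb <- myriad_band(cohort$ref_score)
    cohort$ref_band <- mb$band
    cohort$ref_positive <- mb$positive
  }
  cohort
}
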