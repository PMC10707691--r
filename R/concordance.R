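#' Cross-classify two raters' calls
#'
#' Builds the K x K contingency table of two categorical raters over common
#' levels, for [cohens_kappa()] / [ppa()] / [fisher_exact()].
#'
#' @param a,b class calls of raters A (rows) and B (columns); pairs with an
#'   NA (e.g. undetermined samples) are dropped and the number dropped is
#'   attached as `attr(, "n_dropped")`.
#' @param levels common category order; default: sorted union.
#' @return integer matrix with dimnames.
#' @export
contingency_table <- function(a, b, levels = sort(unique(c(a, b)))) {
  keep <- !is.na(a) & !is.na(b)
  t <- table(factor(a[keep], levels = levels),
             factor(b[keep], levels = levels))
  m <- matrix(as.integer(t), nrow = length(levels),
              dimnames = list(levels, levels))
  attr(m, "n_dropped") <- sum(!keep)
  m
}

#' Interpretation band of a kappa value
#'
#' Standard agreement scale: below 0 no agreement, 0.00-0.20 slight,
#' 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00
#' almost perfect.
#'
#' @param kappa numeric kappa value.
#' @return character label.
#' @export
kappa_interpretation <- function(kappa) {
  stopifnot(is.finite(kappa))
  if (kappa < 0) "no agreement"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Cohen's kappa for a square contingency table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` (diagonal mass) and chance agreement `pe` (product of
#' margins). The p-value tests kappa = 0 by the large-sample normal
#' approximation of kappa's standard error under independence (the exact
#' variance formula of the null distribution); it is approximate for small
#' tables.
#'
#' @param t square integer matrix (raters in identical category order).
#' @return A `kappa_result`: list with `kappa`, `interpretation`
#'   ([kappa_interpretation()]), `p_value`, `po`, `pe`, `n`.
#' @examples
#' t2 <- matrix(c(3, 1, 2, 0, 3, 0, 0, 0, 11), nrow = 3)
#' round(cohens_kappa(t2)$kappa, 3)  # 0.736
#' @export
cohens_kappa <- function(t) {
  t <- as.matrix(t)
  if (nrow(t) != ncol(t)) stop("kappa requires a square table")
  if (any(t < 0)) stop("negative cell counts")
  n <- sum(t)
  if (n == 0) stop("empty table")
  po <- sum(diag(t)) / n
  r <- rowSums(t) / n
  c <- colSums(t) / n
  pe <- sum(r * c)
  if (1 - pe < .Machine$double.eps)
    stop("kappa undefined: chance agreement is 1 (single-category table)")
  kappa <- (po - pe) / (1 - pe)
  # null-hypothesis variance (Fleiss): exact var of kappa under independence
  var0 <- (pe + pe^2 - sum(r * c * (r + c))) / (n * (1 - pe)^2)
  z <- kappa / sqrt(var0)
  structure(list(kappa = kappa,
                 interpretation = kappa_interpretation(kappa),
                 p_value = 2 * pnorm(-abs(z)),
                 po = po, pe = pe, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (%s), p = %.3g, n = %d\n",
              x$kappa, x$interpretation, x$p_value, x$n))
  invisible(x)
}

#' Percent positive agreement (PPA)
#'
#' For a 2 x 2 table with category order (negative, positive), rows = test
#' rater, columns = reference rater: PPA is the both-positive count over the
#' reference-positive column total.
#'
#' @param t 2 x 2 integer matrix, order (negative, positive), columns =
#'   reference.
#' @return list with `ppa` (exact fraction), `percent` (rounded to the
#'   nearest percent), `agree` and `ref_positive` counts.
#' @examples
#' ppa(matrix(c(2, 1, 1, 16), nrow = 2))$percent  # 94
#' @export
ppa <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("PPA requires a 2x2 table")
  ref_pos <- sum(t[, 2])
  if (ref_pos == 0) stop("PPA undefined: no reference-positive samples")
  structure(list(ppa = t[2, 2] / ref_pos,
                 percent = round(100 * t[2, 2] / ref_pos),
                 agree = t[2, 2], ref_positive = ref_pos),
            class = "ppa_result")
}

#' @export
print.ppa_result <- function(x, ...) {
  cat(sprintf("PPA = %d/%d = %d%%\n", x$agree, x$ref_positive, x$percent))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive the mean rank);
#' p-value from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` with
#' n - 2 degrees of freedom. Pairs with a missing value are dropped.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list with `rho`, `p_value`, `n`.
#' @examples
#' spearman_rho(1:4, c(4, 3, 2, 1))$rho  # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Spearman's rho undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by the probability rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables no more probable than the
#' observed one. Delegates to [stats::fisher.test()], which implements
#' exactly this convention.
#'
#' @param t 2 x 2 matrix of non-negative integers.
#' @return list with `p_value` and `odds_ratio` (conditional MLE).
#' @examples
#' fisher_exact(matrix(c(0, 5, 5, 0), nrow = 2))$p_value  # 0.00793...
#' @export
fisher_exact <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2, 2))) stop("fisher_exact requires a 2x2 table")
  if (sum(t) == 0) stop("empty table")
  ft <- fisher.test(t)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}
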