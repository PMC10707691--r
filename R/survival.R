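#' Kaplan-Meier estimate with restricted mean and median
#'
#' Product-limit estimator of the survival function; the mean is the
#' restricted mean survival time (area under the KM step curve up to the
#' largest observed time — with no censoring this equals the arithmetic mean
#' of the times), and the median is the earliest time at which the curve
#' reaches 0.5 (NA, "not reached", if it never does).
#'
#' @param time follow-up times (days, >= 0).
#' @param event event indicator (1 = progression/death, 0 = censored).
#' @return A `km_curve`: list with `time`, `surv`, `n_risk`, `n_event`
#'   (step-curve support), `rmean`, `median`, `n`, `events`.
#' @examples
#' km <- km_estimate(c(5, 10, 15), c(1, 1, 1))
#' km$rmean   # 10
#' km$median  # 10
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one record")
  if (any(time < 0)) stop("times must be >= 0")
  stopifnot(length(event) == length(time), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  tab <- summary(fit, rmean = max(time))$table
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 rmean = unname(tab["rmean"]),
                 median = unname(tab["median"]),
                 n = length(time), events = sum(event)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached" else format(x$median)
  cat(sprintf("KM curve: n = %d, events = %d, restricted mean = %.2f, median = %s\n",
              x$n, x$events, x$rmean, med))
  invisible(x)
}

#' Log-rank test across groups
#'
#' k-sample log-rank test of equality of survival curves; the statistic is
#' referred to a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (>= 2 non-empty groups, >= 1 event in total).
#' @return list with `chisq`, `df`, `p_value`, `n`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("log-rank requires at least two groups")
  if (sum(event) < 1) stop("log-rank requires at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = length(time))
}

#' Univariate Cox proportional-hazards regression on a group factor
#'
#' Partial-likelihood fit (Breslow tie handling) of survival on a single
#' categorical covariate; hazard ratios are relative to the reference
#' (first) level, with Wald 95% confidence intervals and p-values. Monotone
#' likelihood (complete separation, infinite coefficient) is flagged and no
#' estimate is reported for the affected level.
#'
#' @param time,event as in [km_estimate()].
#' @param group covariate (factor or character); first level = reference.
#' @return data.frame with one row per non-reference level: `level`, `hr`,
#'   `ci_lower`, `ci_upper`, `p_value`, `flagged`.
#' @export
cox_univariate <- function(time, event, group) {
  group <- if (is.factor(group)) droplevels(group) else
    as.factor(as.character(group))
  if (nlevels(group) < 2) stop("Cox regression requires >= 2 covariate levels")
  if (sum(event) < 1) stop("Cox regression requires at least one event")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, ties = "breslow"),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  # monotone likelihood: coefficient diverges, SE explodes
  flagged <- !is.finite(beta) | !is.finite(se) | abs(beta) > 15 | se > 100
  hr <- exp(beta)
  z <- beta / se
  out <- data.frame(level = sub("^group", "", names(beta)),
                    hr = ifelse(flagged, NA_real_, hr),
                    ci_lower = ifelse(flagged, NA_real_, exp(beta - 1.96 * se)),
                    ci_upper = ifelse(flagged, NA_real_, exp(beta + 1.96 * se)),
                    p_value = ifelse(flagged, NA_real_, 2 * pnorm(-abs(z))),
                    flagged = flagged,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- levels(group)[1]
  out
}

#' Survival analysis of a cohort by HRD class
#'
#' Per-class Kaplan-Meier summaries (restricted mean and median, in days and
#' months), the log-rank test across classes, and a univariate Cox model
#' with HRN as the reference level. Days are converted to months at
#' 30.4375 days/month for display.
#'
#' @param cohort data.frame with `hrd_class` (or `class3`) plus time/event
#'   columns.
#' @param time_col,event_col column names (default PFS).
#' @return list with `by_class` (data.frame), `logrank`, `cox`.
#' @examples
#' co <- simulate_cohort(40, sim_config(seed = 5))
#' survival_by_class(co)$by_class
#' @export
survival_by_class <- function(cohort, time_col = "pfs_days",
                              event_col = "pfs_event") {
  cls_col <- if ("hrd_class" %in% names(cohort)) "hrd_class" else "class3"
  stopifnot(all(c(cls_col, time_col, event_col) %in% names(cohort)))
  d <- cohort[!is.na(cohort[[cls_col]]), , drop = FALSE]
  classes <- intersect(c("HRD", "HRM", "HRN"), unique(d[[cls_col]]))
  by_class <- do.call(rbind, lapply(classes, function(cl) {
    di <- d[d[[cls_col]] == cl, , drop = FALSE]
    km <- km_estimate(di[[time_col]], di[[event_col]])
    data.frame(class = cl, n = km$n, events = km$events,
               rmean_days = km$rmean, rmean_months = km$rmean / 30.4375,
               median_days = km$median,
               stringsAsFactors = FALSE)
  }))
  lr <- if (length(classes) >= 2 && sum(d[[event_col]]) >= 1)
    logrank_test(d[[time_col]], d[[event_col]], d[[cls_col]])
  else NULL
  cox <- if (length(classes) >= 2 && sum(d[[event_col]]) >= 1)
    cox_univariate(d[[time_col]], d[[event_col]],
                   factor(d[[cls_col]], levels = intersect(
                     c("HRN", "HRM", "HRD"), classes)))
  else NULL
  list(by_class = by_class, logrank = lr, cox = cox)
}
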