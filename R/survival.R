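# Prognostic-biomarker evaluation: Kaplan-Meier curves, log-rank test,
# ROC-derived dichotomisation cutoff, and Pearson correlation of gene pairs.

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, with subjects
#' censored at an event time remaining at risk for that event (events
#' precede censorings at tied times).
#'
#' @param records Data frame with `time` (non-negative) and `event` (0/1)
#'   columns, e.g. from [read_survival()] or [simulate_survival_cohort()].
#' @return Data frame with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(records) {
  if (nrow(records) < 1) fail("need at least one record")
  if (any(records$time < 0)) fail("negative survival time")
  if (!all(records$event %in% c(0, 1))) fail("`event` must be 0 or 1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Log-rank test between two survival groups
#'
#' Standard (O - E)^2 / V chi-square with 1 degree of freedom accumulated
#' over the pooled event times.
#'
#' @param records Survival data frame (`time`, `event`).
#' @param group Vector with exactly two non-empty levels, or the name of a
#'   column of `records`.
#' @return List with `chisq`, `df` and `p_value`.
#' @export
logrank_test <- function(records, group = "group") {
  if (is.character(group) && length(group) == 1L) {
    if (!group %in% names(records)) fail("no column '%s' in records", group)
    group <- records[[group]]
  }
  group <- as.character(group)
  lv <- unique(group)
  if (length(lv) != 2 || any(table(factor(group, lv)) == 0))
    fail("log-rank test needs two non-empty groups")
  if (sum(records$event) < 1) fail("log-rank test needs at least one event")
  d <- data.frame(time = records$time, event = records$event, g = group)
  fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  chisq <- unname(fit$chisq)
  list(chisq = chisq, df = 1L,
       p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' ROC-derived dichotomisation cutoff (Youden index)
#'
#' Scans every midpoint between consecutive distinct marker values, calling
#' marker-above-cutoff positive, and returns the cutoff maximising the
#' Youden index (sensitivity + specificity - 1). Ties go to the lowest such
#' cutoff.
#'
#' @param marker Numeric marker values (e.g. an IHC score).
#' @param outcome Binary outcome (0/1 or logical); both classes must be
#'   present.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
roc_cutoff <- function(marker, outcome) {
  if (length(marker) != length(outcome)) fail("inputs must have equal length")
  outcome <- as.integer(as.logical(outcome))
  if (length(unique(outcome)) < 2)
    fail("both outcome classes must be present")
  u <- sort(unique(marker))
  if (length(u) < 2) fail("marker must take at least two distinct values")
  cuts <- (u[-1] + u[-length(u)]) / 2
  n_pos <- sum(outcome == 1)
  n_neg <- sum(outcome == 0)
  best <- list(youden = -Inf)
  for (ct in cuts) {
    sens <- sum(marker > ct & outcome == 1) / n_pos
    spec <- sum(marker <= ct & outcome == 0) / n_neg
    y <- sens + spec - 1
    if (y > best$youden) {
      best <- list(cutoff = ct, sensitivity = sens, specificity = spec,
                   youden = y)
    }
  }
  best
}

#' Pearson correlation with t-distribution p-value
#'
#' Sample correlation `r` with two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be constant.
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) fail("`x` and `y` must have equal length")
  if (length(x) < 3) fail("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    fail("constant vector: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Dichotomise a cohort at a marker cutoff and compare survival
#'
#' Patients with marker strictly above the cutoff form the `high` group. If
#' no cutoff is supplied it is derived by [roc_cutoff()] against the event
#' indicator. Returns per-group Kaplan-Meier curves and the log-rank
#' comparison.
#'
#' @param records Survival data frame (`time`, `event`, `marker`).
#' @param cutoff Marker cutoff; must split the cohort into two non-empty
#'   groups.
#' @return List with `cutoff`, `group` (per-record labels), `km` (named list
#'   of per-group KM curves) and `logrank`.
#' @export
dichotomize_and_compare <- function(records, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- roc_cutoff(records$marker, records$event)$cutoff
  grp <- ifelse(records$marker > cutoff, "high", "low")
  if (length(unique(grp)) < 2)
    fail("cutoff %s leaves one group empty (outside the marker range)",
         format(cutoff))
  list(cutoff = cutoff,
       group = grp,
       km = list(high = km_estimate(records[grp == "high", , drop = FALSE]),
                 low = km_estimate(records[grp == "low", , drop = FALSE])),
       logrank = logrank_test(records, grp))
}
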