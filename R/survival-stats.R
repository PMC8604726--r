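#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimate of the survival function with right censoring.
#' The median is the earliest time at which the estimated survival drops to
#' 0.5 or below, or not-reached (`NA`); its confidence interval uses the
#' log-log transform (Brookmeyer-Crowley).
#'
#' @param times Event/censoring times (months, >= 0).
#' @param events Logical (or 0/1) event indicators; `FALSE` = censored.
#' @param level Confidence level. Default 0.95.
#' @return Object of class `lt_km` wrapping a [survival::survfit] object,
#'   with `median`, `median_lower`, `median_upper` (months; `NA` =
#'   not reached). Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' km_fit(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
km_fit <- function(times, events, level = 0.95) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) abort("no observations")
  if (any(times < 0)) abort("times must be >= 0")
  events <- as.logical(events)
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = "log-log", conf.int = level
  )
  q <- stats::quantile(fit, probs = 0.5)
  # earliest time at which survival reaches 0.5 or below; survfit's own
  # median interpolates when S(t) hits exactly 0.5
  drop_idx <- which(fit$surv <= 0.5 + 1e-9)
  structure(
    list(
      fit = fit,
      n = length(times), n_event = sum(events), level = level,
      median = if (length(drop_idx)) fit$time[drop_idx[1]] else NA_real_,
      median_lower = unname(q$lower),
      median_upper = unname(q$upper)
    ),
    class = "lt_km"
  )
}

#' @export
print.lt_km <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NR", sprintf("%.1f", v))
  cat(sprintf(
    "Kaplan-Meier fit: n = %d, events = %d\n  median %s months (%d%% CI %s-%s)\n",
    x$n, x$n_event, fmt(x$median), round(100 * x$level),
    fmt(x$median_lower), fmt(x$median_upper)
  ))
  invisible(x)
}

#' Cox proportional-hazards ratio for a binary factor
#'
#' Maximum-partial-likelihood hazard ratio for a two-level grouping (Efron
#' tie handling) with a Wald confidence interval. The hazard ratio is for
#' `group = TRUE` relative to `group = FALSE`. When one group has no events
#' the partial likelihood is monotone and the CI is effectively unbounded; a
#' warning is raised.
#'
#' @inheritParams km_fit
#' @param group Logical vector: the factor level whose hazard is compared to
#'   the reference (`FALSE`) level.
#' @return Tibble: `hr`, `conf_low`, `conf_high`, `p_value`, `n`, `n_event`.
#' @export
cox_hr_binary <- function(times, events, group, level = 0.95) {
  events <- as.logical(events)
  group <- as.logical(group)
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (length(unique(group)) < 2) abort("both group levels must be present")
  if (any(tapply(events, group, sum) == 0)) {
    warn("a group has no events: partial likelihood is monotone, CI unbounded")
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ group, ties = "efron")
  est <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    hr = exp(est),
    conf_low = exp(est - z * se),
    conf_high = exp(est + z * se),
    p_value = 2 * pnorm(-abs(est / se)),
    n = length(times),
    n_event = sum(events)
  )
}

#' Log-rank test for two groups
#'
#' Two-sided log-rank chi-square test on one degree of freedom.
#'
#' @inheritParams cox_hr_binary
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.logical(group)
  if (length(unique(group)) < 2) abort("two groups are required")
  sd <- survival::survdiff(survival::Surv(times, as.logical(events)) ~ group)
  tibble(
    statistic = sd$chisq,
    df = 1,
    p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The p-value is exact (by
#' enumeration of the permutation distribution) when the combined sample size
#' is at most 20 and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @return Tibble: `u` (number of (x, y) pairs with x > y, ties counting
#'   half), `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  tibble(
    u = unname(wt$statistic),
    p_value = wt$p.value,
    method = ifelse(use_exact, "exact", "normal_approx")
  )
}
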