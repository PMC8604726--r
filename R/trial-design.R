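#' Critical value of the exact single-stage binomial design
#'
#' The smallest number of responses `r` such that observing `r` or more
#' responses among `n` patients has probability at most `alpha` under the
#' null response rate `p0`: `P(X >= r | n, p0) <= alpha` with
#' `X ~ Binom(n, p0)`.
#'
#' @param n Number of patients.
#' @param p0 Null response rate, in (0, 1).
#' @param alpha One-sided type-I error level, in (0, 1).
#' @return Integer critical value `r` (in `1..n`).
#' @export
#' @examples
#' design_critical_value(25, 0.05, 0.025) # 5 responses needed
design_critical_value <- function(n, p0, alpha) {
  stopifnot(n >= 1, p0 > 0, p0 < 1, alpha > 0, alpha < 1)
  tails <- pbinom(0:n - 1, n, p0, lower.tail = FALSE) # P(X >= r), r = 0..n
  ok <- which(tails <= alpha) - 1L
  ok <- ok[ok <= n]
  if (length(ok) == 0) {
    abort(sprintf("no critical value r <= n = %d attains one-sided alpha = %g", n, alpha))
  }
  min(ok)
}

#' Exact single-stage phase-II design
#'
#' Sizes the exact single-stage binomial design: reject the null response
#' rate `p0` when at least `r = design_critical_value(n, p0, alpha)`
#' responses are observed among `n` patients.
#'
#' Because the critical value is an integer, the attained power of the exact
#' design is a saw-tooth in `n`: it can dip back below the target when `r`
#' jumps. The returned `n` is therefore the smallest sample size from which
#' the power stays at or above `power` for *every* larger sample size (up to
#' `n_max`) -- the convention of the standard single-stage design tables,
#' which guarantees the stated power even if accrual slightly exceeds plan.
#' (A naive "first n whose power crosses the target" scan can return a
#' smaller n sitting just before a power dip.)
#'
#' @param p0 Null (uninteresting) response rate.
#' @param p1 Alternative (target) response rate; must exceed `p0`.
#' @param alpha One-sided type-I error level.
#' @param power Required power at `p1`.
#' @param n_max Search ceiling for `n`. Default 1000.
#' @return Object of class `lt_design`: list with `n`, `r`, `p0`, `p1`,
#'   `alpha`, `power_target`, `attained_alpha` (= `P(X >= r | n, p0)`) and
#'   `power` (= `P(X >= r | n, p1)`). Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' single_stage_design(p0 = 0.05, p1 = 0.30, alpha = 0.025, power = 0.90)
single_stage_design <- function(p0, p1, alpha = 0.025, power = 0.90, n_max = 1000) {
  stopifnot(p1 > p0, p0 > 0, p1 <= 1, power > 0, power < 1)
  rs <- vapply(seq_len(n_max), function(n) {
    tryCatch(design_critical_value(n, p0, alpha), error = function(e) NA_integer_)
  }, integer(1))
  pw <- ifelse(is.na(rs), -Inf,
    pbinom(rs - 1, seq_len(n_max), p1, lower.tail = FALSE)
  )
  ok <- pw >= power
  if (!ok[n_max]) {
    abort(sprintf("no design with power %g found for n <= %d", power, n_max))
  }
  n <- if (all(ok)) which(ok)[1] else max(which(!ok)) + 1L
  structure(
    list(
      n = n, r = rs[n], p0 = p0, p1 = p1, alpha = alpha, power_target = power,
      attained_alpha = pbinom(rs[n] - 1, n, p0, lower.tail = FALSE),
      power = pw[n]
    ),
    class = "lt_design"
  )
}

#' @export
print.lt_design <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Exact single-stage binomial design\n",
      "  H0: p <= %g vs H1: p = %g, one-sided alpha = %g\n",
      "  n = %d patients; reject H0 at >= %d responses\n",
      "  attained alpha = %.4f, power = %.4f\n"
    ),
    x$p0, x$p1, x$alpha, x$n, x$r, x$attained_alpha, x$power
  ))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided interval obtained by inverting binomial tail
#' probabilities, computed in the beta-quantile formulation:
#' lower = `qbeta(a/2, x, n - x + 1)` (0 when `x = 0`) and
#' upper = `qbeta(1 - a/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Successes (vectorised).
#' @param n Trials.
#' @param level Confidence level. Default 0.95.
#' @return Tibble with `x`, `n`, `level`, `estimate`, `lower`, `upper`.
#' @export
#' @examples
#' clopper_pearson(8, 27) # 30% (95% CI 14-50%)
clopper_pearson <- function(x, n, level = 0.95) {
  m <- max(length(x), length(n))
  x <- rep_len(x, m)
  n <- rep_len(n, m)
  if (any(x < 0 | x > n | n < 1)) abort("need 0 <= x <= n, n >= 1")
  stopifnot(level > 0, level < 1)
  a <- 1 - level
  tibble(
    x = x, n = n, level = level,
    estimate = x / n,
    lower = ifelse(x == 0, 0, qbeta(a / 2, x, n - x + 1)),
    upper = ifelse(x == n, 1, qbeta(1 - a / 2, x + 1, n - x))
  )
}

#' Objective response rate with exact confidence interval
#'
#' The confirmed objective response rate: the proportion of patients whose
#' best confirmed response is CR or PR, with a Clopper-Pearson interval.
#' Percentages are rounded half-up to integers for report parity.
#'
#' @param records Per-patient records ([clinical_records()] output) with a
#'   `best_confirmed` column.
#' @param level Confidence level for the exact interval.
#' @return Tibble: `n`, `responders`, `orr` (proportion), `orr_pct` (integer
#'   percent), `lower`, `upper` (proportions), `lower_pct`, `upper_pct`.
#' @export
orr <- function(records, level = 0.95) {
  if (nrow(records) == 0) abort("no records")
  x <- sum(records$best_confirmed %in% c("CR", "PR"))
  n <- nrow(records)
  ci <- clopper_pearson(x, n, level)
  tibble(
    n = n, responders = x,
    orr = x / n, orr_pct = round_half_up(100 * x / n),
    lower = ci$lower, upper = ci$upper,
    lower_pct = round_half_up(100 * ci$lower),
    upper_pct = round_half_up(100 * ci$upper)
  )
}
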