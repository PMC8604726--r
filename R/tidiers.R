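#' Tidiers for fitted liquidtrial objects
#'
#' Broom-style [generics::tidy()] and [generics::glance()] methods. `tidy()`
#' returns the component-level table of an object (ROC operating points, KM
#' curve steps, design summary row); `glance()` returns a one-row summary.
#'
#' @param x The fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name liquidtrial-tidiers
NULL

#' @rdname liquidtrial-tidiers
#' @export
tidy.lt_roc <- function(x, ...) {
  x$operating_points
}

#' @rdname liquidtrial-tidiers
#' @export
glance.lt_roc <- function(x, ...) {
  tibble(
    auroc = x$auroc, p_value = x$p_value,
    chosen_threshold = x$chosen_threshold,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname liquidtrial-tidiers
#' @export
tidy.lt_design <- function(x, ...) {
  tibble(
    n = x$n, r = x$r, p0 = x$p0, p1 = x$p1, alpha = x$alpha,
    attained_alpha = x$attained_alpha, power = x$power
  )
}

#' @rdname liquidtrial-tidiers
#' @export
glance.lt_design <- function(x, ...) tidy(x)

#' @rdname liquidtrial-tidiers
#' @export
tidy.lt_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  tibble(
    time = s$time, n_risk = s$n.risk, n_event = s$n.event,
    n_censor = s$n.censor, estimate = s$surv,
    conf_low = s$lower, conf_high = s$upper
  )
}

#' @rdname liquidtrial-tidiers
#' @export
glance.lt_km <- function(x, ...) {
  tibble(
    n = x$n, n_event = x$n_event,
    median = x$median, median_lower = x$median_lower,
    median_upper = x$median_upper, level = x$level
  )
}
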