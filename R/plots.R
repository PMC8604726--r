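#' Plot methods for liquidtrial results
#'
#' `autoplot.lt_roc()` draws the ROC curve with the Youden-selected operating
#' point highlighted; `autoplot.lt_km()` draws the Kaplan-Meier step curve
#' with its confidence band; `plot_change_by_response()` shows per-patient
#' week-3/baseline ctDNA-fraction ratios by response group on a log-friendly
#' square-root scale with the group medians.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name liquidtrial-plots
NULL

#' @rdname liquidtrial-plots
#' @export
autoplot.lt_roc <- function(object, ...) {
  pts <- object$operating_points %>%
    arrange(dplyr::desc(.data$threshold))
  df <- bind_rows(
    tibble(fpr = 0, tpr = 0),
    tibble(fpr = 1 - pts$specificity, tpr = pts$sensitivity),
    tibble(fpr = 1, tpr = 1)
  )
  chosen <- pts[pts$threshold == object$chosen_threshold, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(
      data = tibble(fpr = 1 - chosen$specificity, tpr = chosen$sensitivity),
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUROC = %.2f (P = %.3g)", object$auroc, object$p_value)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @rdname liquidtrial-plots
#' @export
autoplot.lt_km <- function(object, ...) {
  d <- tidy(object)
  d0 <- bind_rows(tibble(
    time = 0, n_risk = object$n, n_event = 0L, n_censor = 0L,
    estimate = 1, conf_low = 1, conf_high = 1
  ), d)
  cens <- d[d$n_censor > 0, ]
  ggplot2::ggplot(d0, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = "dotted", na.rm = TRUE) +
    ggplot2::geom_point(data = cens, shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' @rdname liquidtrial-plots
#' @param changes Output of [ctdna_change_table()].
#' @param records Output of [clinical_records()].
#' @export
plot_change_by_response <- function(changes, records) {
  med <- summarize_change_by_response(changes, records)
  d <- changes %>%
    dplyr::inner_join(
      select(records, "patient_id", "best_confirmed", "best_sld_change"),
      by = "patient_id"
    ) %>%
    filter(.data$best_confirmed %in% c("CR", "PR", "SD", "PD")) %>%
    mutate(response_group = factor(case_when(
      .data$best_confirmed == "SD" & !is.na(.data$best_sld_change) &
        .data$best_sld_change < 0 ~ "SD_shrinkage",
      .data$best_confirmed == "SD" ~ "SD_no_shrinkage",
      TRUE ~ .data$best_confirmed
    ), levels = levels(med$response_group)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response_group, y = .data$ratio)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_point(
      data = med, ggplot2::aes(y = .data$median_ratio),
      colour = "red", shape = 95, size = 10
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(
      x = "Best confirmed response",
      y = "Week-3 / baseline ctDNA fraction"
    ) +
    ggplot2::theme_minimal()
}
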