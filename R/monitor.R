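RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE")

resp_rank <- function(category) match(category, RESPONSE_LEVELS)

#' Best confirmed response from an assessment series
#'
#' RECIST-style confirmation at desk scale: a CR or PR counts as the best
#' confirmed response only if a later assessment at least 28 days (4 weeks)
#' after the initial response shows the same or a better category. An
#' unconfirmed CR/PR is demoted to the best non-response category actually
#' observed in the series (SD over PD); when the series contains no SD/PD at
#' all, an unconfirmed response is reported as SD (the disease demonstrably
#' did not progress at that assessment). A series with only NE assessments is
#' NE.
#'
#' @param assessments Data frame with columns `day` (days from treatment
#'   start, >= 0) and `category` (`"CR"`, `"PR"`, `"SD"`, `"PD"`, `"NE"`).
#' @param confirm_days Minimum gap for confirmation; default 28 (inclusive).
#' @return Single category string.
#' @export
#' @examples
#' confirm_best_response(data.frame(day = c(42, 84), category = c("PR", "PR"))) # "PR"
#' confirm_best_response(data.frame(day = c(42, 84), category = c("PR", "PD"))) # "PD"
confirm_best_response <- function(assessments, confirm_days = 28) {
  stopifnot(is.data.frame(assessments))
  if (nrow(assessments) == 0) abort("assessment series is empty")
  if (any(assessments$day < 0)) abort("assessment day must be >= 0")
  if (!all(assessments$category %in% RESPONSE_LEVELS)) {
    abort(paste("category must be one of", paste(RESPONSE_LEVELS, collapse = ", ")))
  }
  a <- assessments[order(assessments$day), , drop = FALSE]
  confirmed <- function(resp) {
    idx <- which(a$category == resp)
    any(vapply(idx, function(i) {
      later <- a$day >= a$day[i] + confirm_days
      any(later & resp_rank(a$category) <= resp_rank(resp))
    }, logical(1)))
  }
  if (confirmed("CR")) return("CR")
  if (confirmed("PR")) return("PR")
  non_resp <- intersect(c("SD", "PD"), a$category)
  if (length(non_resp)) {
    # ties to the better (SD beats PD as "best" observed)
    return(non_resp[1])
  }
  if (any(a$category %in% c("CR", "PR"))) return("SD")
  "NE"
}

#' Clinical benefit classification
#'
#' Clinical benefit is a confirmed radiographic response (CR or PR) or stable
#' disease lasting four or more months (inclusive at exactly 4.0 months).
#'
#' @param best_confirmed Character vector of best confirmed response
#'   categories.
#' @param pfs_months Numeric vector of progression-free survival in months
#'   (days / 30.4375); required (non-`NA`) wherever `best_confirmed == "SD"`.
#' @return Logical vector.
#' @export
#' @examples
#' classify_benefit(c("PR", "SD", "SD"), c(2.0, 4.0, 3.9)) # TRUE TRUE FALSE
classify_benefit <- function(best_confirmed, pfs_months) {
  stopifnot(length(best_confirmed) == length(pfs_months))
  if (any(best_confirmed == "SD" & is.na(pfs_months))) {
    abort("PFS is required to classify benefit for stable disease")
  }
  best_confirmed %in% c("CR", "PR") |
    (best_confirmed == "SD" & !is.na(pfs_months) & pfs_months >= 4.0)
}

#' Per-patient clinical records from the long clinical table
#'
#' Collapses the per-assessment clinical table to one row per patient with
#' the derived best confirmed response, best (most negative) change in the
#' sum of longest diameters, and the benefit flag.
#'
#' @param clinical Clinical table (see [read_clinical_table()] for the
#'   schema): one row per assessment with survival columns repeated.
#' @return Tibble with one row per patient: `patient_id`, `best_confirmed`,
#'   `best_sld_change`, `benefit`, `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event` (plus `week3_collected` if present in the input).
#' @export
clinical_records <- function(clinical) {
  keep <- intersect(
    c("pfs_months", "pfs_event", "os_months", "os_event", "week3_collected"),
    names(clinical)
  )
  clinical %>%
    group_by(.data$patient_id) %>%
    summarise(
      best_confirmed = confirm_best_response(
        data.frame(day = .data$assessment_day, category = .data$assessment_category)
      ),
      best_sld_change = if (all(is.na(.data$sld_change_percent))) NA_real_ else
        min(.data$sld_change_percent, na.rm = TRUE),
      dplyr::across(dplyr::all_of(keep), dplyr::first),
      .groups = "drop"
    ) %>%
    mutate(benefit = classify_benefit(.data$best_confirmed, .data$pfs_months))
}

#' Proportional change in ctDNA fraction over the first weeks on treatment
#'
#' The ratio of the week-3 ctDNA fraction to the baseline ctDNA fraction. A
#' week-3 sample in which no somatic variant is detected represents complete
#' ctDNA clearance and gets ratio 0 (pass `week3_fraction = 0` or `NA` for
#' such samples). The change is undefined when the baseline fraction is 0 or
#' missing. Direction is `"decreased"` strictly below 1 and `"increased"` at
#' 1 or above.
#'
#' @param baseline_fraction,week3_fraction Numeric vectors of ctDNA
#'   (tumor) fractions; any common scale works -- the ratio is
#'   scale-invariant.
#' @return Tibble with `baseline_fraction`, `week3_fraction`, `ratio`,
#'   `direction`.
#' @export
#' @examples
#' ctdna_change(0.2, 0.064) # ratio 0.32, decreased
#' ctdna_change(0.2, NA)    # complete clearance: ratio 0
ctdna_change <- function(baseline_fraction, week3_fraction) {
  n <- max(length(baseline_fraction), length(week3_fraction))
  baseline_fraction <- rep_len(baseline_fraction, n)
  week3_fraction <- rep_len(week3_fraction, n)
  if (any(is.na(baseline_fraction) | baseline_fraction <= 0)) {
    abort("baseline ctDNA fraction must be detectable (> 0): change is undefined",
      class = "liquidtrial_undefined_change"
    )
  }
  wk3 <- ifelse(is.na(week3_fraction), 0, week3_fraction)
  ratio <- wk3 / baseline_fraction
  tibble(
    baseline_fraction = baseline_fraction,
    week3_fraction = wk3,
    ratio = ratio,
    direction = ifelse(ratio < 1, "decreased", "increased")
  )
}

#' Cohort-level ctDNA-change table
#'
#' Computes the per-patient proportional change in ctDNA fraction between the
#' baseline and week-3 plasma samples of a variant table. Only patients with
#' a detectable baseline fraction and a collected week-3 sample are included:
#' a collected week-3 sample with no somatic call means clearance (ratio 0),
#' whereas an uncollected sample means the change is unknown. Collection
#' status is taken from the `week3_collected` column of `clinical` when
#' supplied; otherwise any patient with week-3 rows in `variants` is treated
#' as collected and the rest are dropped.
#'
#' @param variants Variant table with baseline and week3 plasma samples.
#' @param clinical Optional clinical table carrying `week3_collected`.
#' @return Tibble: `patient_id`, `baseline_fraction`, `week3_fraction`,
#'   `ratio`, `direction`.
#' @export
ctdna_change_table <- function(variants, clinical = NULL) {
  fr <- ctdna_fraction(variants)
  base <- fr %>%
    filter(.data$timepoint == "baseline", !is.na(.data$tumor_fraction), .data$tumor_fraction > 0) %>%
    select("patient_id", baseline_fraction = "tumor_fraction")
  wk3 <- fr %>%
    filter(.data$timepoint == "week3") %>%
    select("patient_id", week3_fraction = "tumor_fraction")
  collected <- if (!is.null(clinical) && "week3_collected" %in% names(clinical)) {
    unique(clinical$patient_id[clinical$week3_collected])
  } else {
    unique(wk3$patient_id)
  }
  out <- base %>%
    filter(.data$patient_id %in% collected) %>%
    left_join(wk3, by = "patient_id")
  dplyr::bind_cols(
    select(out, "patient_id"),
    ctdna_change(out$baseline_fraction, out$week3_fraction)
  )
}

#' Median ctDNA-fraction change by response category
#'
#' Summarises per-patient week-3/baseline ctDNA-fraction ratios by the best
#' confirmed response, splitting stable disease by whether the best
#' sum-of-longest-diameters change shows tumor shrinkage (SLD change < 0;
#' exactly 0 counts as no shrinkage). Categories with no patients are absent
#' from the output.
#'
#' @param changes Output of [ctdna_change_table()].
#' @param records Output of [clinical_records()] (needs `best_confirmed`,
#'   `best_sld_change`).
#' @return Tibble: `response_group` (factor: CR, PR, SD_shrinkage,
#'   SD_no_shrinkage, PD), `n`, `median_ratio`.
#' @export
summarize_change_by_response <- function(changes, records) {
  groups <- c("CR", "PR", "SD_shrinkage", "SD_no_shrinkage", "PD")
  changes %>%
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
    ), levels = groups)) %>%
    group_by(.data$response_group) %>%
    summarise(n = dplyr::n(), median_ratio = median(.data$ratio), .groups = "drop") %>%
    arrange(.data$response_group)
}
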