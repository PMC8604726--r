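alteration_key <- function(df) {
  lbl <- if ("variant_label" %in% names(df)) df$variant_label else NA_character_
  paste(df$gene, df$alteration_type, ifelse(is.na(lbl), "", lbl), sep = "|")
}

#' Paired baseline/progression profile comparison for one patient
#'
#' Identifies alterations that emerged at disease progression (present at
#' progression, absent at baseline) and alterations that were lost
#' (present at baseline, absent at progression). Identity is presence/absence
#' of the (gene, alteration type, variant label) key -- VAF or copy-number
#' dosage changes are not compared. Loss of an amplification means the call
#' is absent at progression (it fell below the assay's reportable range), not
#' that the adjusted copy number decreased.
#'
#' @param baseline,progression Variant tables (plasma rows) for the same
#'   patient at the two timepoints; an empty data frame represents a sample
#'   with no somatic call.
#' @param actionable Gene set defining actionable emergent alterations.
#'   Default [actionable_genes()].
#' @return List of class `lt_resistance`: `patient_id`, `emergent`, `lost`
#'   (tibbles of variant rows), `emergent_actionable`, `her2_amp_lost`.
#' @export
diff_profiles <- function(baseline, progression, actionable = actionable_genes()) {
  pids <- unique(c(baseline$patient_id, progression$patient_id))
  if (length(pids) > 1) {
    abort(sprintf(
      "baseline and progression profiles are from different patients: %s",
      paste(pids, collapse = ", ")
    ))
  }
  bkey <- alteration_key(baseline)
  pkey <- alteration_key(progression)
  emergent <- as_tibble(progression[!(pkey %in% bkey), , drop = FALSE])
  lost <- as_tibble(baseline[!(bkey %in% pkey), , drop = FALSE])
  structure(
    list(
      patient_id = if (length(pids)) pids else NA_character_,
      emergent = emergent,
      lost = lost,
      emergent_actionable = emergent[emergent$gene %in% actionable, , drop = FALSE],
      her2_amp_lost = any(lost$gene == "ERBB2" & lost$alteration_type == "amplification")
    ),
    class = "lt_resistance"
  )
}

#' @export
print.lt_resistance <- function(x, ...) {
  cat(sprintf(
    "Resistance comparison for %s: %d emergent (%d actionable), %d lost%s\n",
    x$patient_id, nrow(x$emergent), nrow(x$emergent_actionable), nrow(x$lost),
    if (x$her2_amp_lost) ", HER2 amplification lost" else ""
  ))
  invisible(x)
}

#' Cohort-wide acquired-resistance report
#'
#' Runs [diff_profiles()] for every patient with both a baseline and a
#' progression plasma sample and returns one summary row per patient. A
#' patient whose progression sample has no somatic call still counts (all
#' baseline alterations, including the HER2 amplification, are lost).
#'
#' @param variants Variant table with baseline and progression plasma rows.
#' @param actionable Actionable gene set.
#' @param patients Optional character vector restricting/extending the
#'   patient set (e.g. patients whose progression draw yielded no call and
#'   who therefore have no progression rows); defaults to patients with
#'   progression rows.
#' @return Tibble: `patient_id`, `n_emergent`, `n_lost`,
#'   `n_emergent_actionable`, `any_emergent_actionable`, `her2_amp_lost`.
#' @export
resistance_report <- function(variants, actionable = actionable_genes(),
                              patients = NULL) {
  pl <- filter(variants, .data$sample_type == "plasma")
  if (is.null(patients)) {
    patients <- unique(pl$patient_id[pl$timepoint == "progression"])
  }
  patients <- intersect(patients, unique(pl$patient_id[pl$timepoint == "baseline"]))
  purrr::map_dfr(patients, function(p) {
    d <- diff_profiles(
      filter(pl, .data$patient_id == p, .data$timepoint == "baseline"),
      filter(pl, .data$patient_id == p, .data$timepoint == "progression"),
      actionable = actionable
    )
    tibble(
      patient_id = p,
      n_emergent = nrow(d$emergent),
      n_lost = nrow(d$lost),
      n_emergent_actionable = nrow(d$emergent_actionable),
      any_emergent_actionable = nrow(d$emergent_actionable) > 0,
      her2_amp_lost = d$her2_amp_lost
    )
  })
}

#' Cohort resistance counts
#'
#' @param report Output of [resistance_report()].
#' @return Tibble with `n_patients`, `n_emergent_actionable` (patients with
#'   at least one actionable emergent alteration), `pct_emergent_actionable`
#'   (integer percent, half-up), `n_her2_amp_lost`.
#' @export
#' @examples
#' rep <- tibble::tibble(any_emergent_actionable = rep(c(TRUE, FALSE), c(16, 10)),
#'                       her2_amp_lost = rep(c(TRUE, FALSE), c(4, 22)))
#' cohort_resistance_summary(rep) # 16/26 = 62%
cohort_resistance_summary <- function(report) {
  if (nrow(report) == 0) abort("resistance report is empty")
  tibble(
    n_patients = nrow(report),
    n_emergent_actionable = sum(report$any_emergent_actionable),
    pct_emergent_actionable =
      round_half_up(100 * sum(report$any_emergent_actionable) / nrow(report)),
    n_her2_amp_lost = sum(report$her2_amp_lost)
  )
}
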