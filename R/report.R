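#' Run the full biomarker analysis on a cohort
#'
#' Chains every analysis stage on a variant + clinical table pair: ctDNA
#' metrics, per-modality baseline biomarker status, ROC of adjusted versus
#' raw plasma HER2 copy number (and tissue NGS CN) against clinical benefit,
#' favorable-factor classification and its PFS/OS stratification, week-3
#' ctDNA-fraction monitoring, acquired-resistance summary, and the trial's
#' ORR / Kaplan-Meier estimates.
#'
#' @param variants Variant table.
#' @param clinical Clinical table.
#' @param cn_threshold Copy-number thresholds used for favorable
#'   classification on the ctDNA (ApCN) scale; `NULL` (default) selects it
#'   from the cohort by ROC/Youden.
#' @param tissue_cn_threshold Same for the tissue NGS CN scale; `NULL`
#'   selects by ROC.
#' @param gene_set Pathway gene set for the co-alteration screen.
#' @param actionable Actionable gene set for the resistance summary.
#' @return List of class `lt_analysis` with elements `records`, `orr`,
#'   `km_pfs`, `km_os`, `status_ctdna`, `status_tissue`, `roc_apcn`,
#'   `roc_pcn`, `roc_tissue`, `ctdna_threshold`, `tissue_threshold`,
#'   `favorable_ctdna`, `hr_favorable`, `hr_favorable_os`, `changes`,
#'   `change_summary`, `hr_decreased`, `resistance`, `resistance_summary`.
#'   ROC and HR elements are `NULL` when the cohort cannot support them
#'   (e.g. a single outcome class).
#' @export
analyze_cohort <- function(variants, clinical,
                           cn_threshold = NULL, tissue_cn_threshold = NULL,
                           gene_set = rtk_ras_pi3k_genes(),
                           actionable = actionable_genes()) {
  records <- clinical_records(clinical)

  status_ct <- biomarker_status(variants, "ctdna", gene_set)
  status_ti <- biomarker_status(variants, "tissue", gene_set)
  pcn_raw <- variants %>%
    filter(
      .data$sample_type == "plasma", .data$timepoint == "baseline",
      .data$gene == "ERBB2", .data$alteration_type == "amplification"
    ) %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    select("patient_id", pcn = "plasma_cn")

  roc_of <- function(scores_df, col) {
    d <- dplyr::inner_join(scores_df, select(records, "patient_id", "benefit"),
      by = "patient_id"
    )
    d <- d[!is.na(d[[col]]), ]
    if (nrow(d) < 2 || length(unique(d$benefit)) < 2) {
      return(NULL)
    }
    roc_curve(d[[col]], d$benefit)
  }
  roc_apcn <- roc_of(status_ct, "her2_cn_value")
  roc_pcn <- roc_of(pcn_raw, "pcn")
  roc_tissue <- roc_of(status_ti, "her2_cn_value")

  ct_thr <- cn_threshold %||%
    (if (!is.null(roc_apcn)) select_threshold(roc_apcn) else NA_real_)
  ti_thr <- tissue_cn_threshold %||%
    (if (!is.null(roc_tissue)) select_threshold(roc_tissue) else NA_real_)

  fav <- NULL
  hr_fav <- NULL
  hr_fav_os <- NULL
  if (!is.na(ct_thr)) {
    fav <- classify_favorable(status_ct, ct_thr) %>%
      dplyr::inner_join(
        select(records, "patient_id", "pfs_months", "pfs_event", "os_months", "os_event"),
        by = "patient_id"
      )
    if (length(unique(fav$favorable)) == 2) {
      hr_fav <- cox_hr_binary(fav$pfs_months, fav$pfs_event, fav$favorable)
      hr_fav_os <- cox_hr_binary(fav$os_months, fav$os_event, fav$favorable)
    }
  }

  changes <- ctdna_change_table(variants, clinical)
  change_summary <- summarize_change_by_response(changes, records)
  hr_dec <- NULL
  chg <- dplyr::inner_join(changes,
    select(records, "patient_id", "pfs_months", "pfs_event"),
    by = "patient_id"
  )
  if (length(unique(chg$direction)) == 2) {
    hr_dec <- cox_hr_binary(chg$pfs_months, chg$pfs_event, chg$direction == "decreased")
  }

  prog_pat <- if ("progression_collected" %in% names(clinical)) {
    unique(clinical$patient_id[clinical$progression_collected])
  } else {
    NULL
  }
  resistance <- resistance_report(variants, actionable, patients = prog_pat)
  resistance_summary <- if (nrow(resistance)) cohort_resistance_summary(resistance) else NULL

  structure(
    list(
      records = records,
      orr = orr(records),
      km_pfs = km_fit(records$pfs_months, records$pfs_event),
      km_os = km_fit(records$os_months, records$os_event),
      status_ctdna = status_ct, status_tissue = status_ti,
      roc_apcn = roc_apcn, roc_pcn = roc_pcn, roc_tissue = roc_tissue,
      ctdna_threshold = ct_thr, tissue_threshold = ti_thr,
      favorable_ctdna = fav,
      hr_favorable = hr_fav, hr_favorable_os = hr_fav_os,
      changes = changes, change_summary = change_summary,
      hr_decreased = hr_dec,
      resistance = resistance, resistance_summary = resistance_summary
    ),
    class = "lt_analysis"
  )
}

#' @export
print.lt_analysis <- function(x, ...) {
  o <- x$orr
  cat(sprintf(
    "Cohort analysis: %d patients\n  Confirmed ORR: %d/%d = %d%% (95%% CI %d-%d%%)\n",
    o$n, o$responders, o$n, o$orr_pct, o$lower_pct, o$upper_pct
  ))
  fmt <- function(v) ifelse(is.na(v), "NR", sprintf("%.1f", v))
  cat(sprintf(
    "  Median PFS %s mo, median OS %s mo\n",
    fmt(x$km_pfs$median), fmt(x$km_os$median)
  ))
  if (!is.null(x$roc_apcn)) {
    cat(sprintf(
      "  Benefit AUROC: ApCN %.3f vs raw pCN %s; ctDNA threshold %.1f copies\n",
      x$roc_apcn$auroc,
      ifelse(is.null(x$roc_pcn), "NA", sprintf("%.3f", x$roc_pcn$auroc)),
      x$ctdna_threshold
    ))
  }
  if (!is.null(x$hr_favorable)) {
    cat(sprintf(
      "  Favorable-factor PFS HR %.2f (95%% CI %.2f-%.2f)\n",
      x$hr_favorable$hr, x$hr_favorable$conf_low, x$hr_favorable$conf_high
    ))
  }
  if (!is.null(x$hr_decreased)) {
    cat(sprintf(
      "  Decreased week-3 ctDNA PFS HR %.2f (95%% CI %.2f-%.2f)\n",
      x$hr_decreased$hr, x$hr_decreased$conf_low, x$hr_decreased$conf_high
    ))
  }
  if (!is.null(x$resistance_summary)) {
    rs <- x$resistance_summary
    cat(sprintf(
      "  Acquired resistance: %d/%d (%d%%) with emergent actionable alteration; HER2 amp lost in %d\n",
      rs$n_emergent_actionable, rs$n_patients, rs$pct_emergent_actionable, rs$n_her2_amp_lost
    ))
  }
  invisible(x)
}

#' Write the headline analysis tables to a directory
#'
#' Exports every headline table of an [analyze_cohort()] result as TSV files
#' under `out_dir`, plus a `report_header.tsv` recording the run's seed (if
#' given) and thresholds for reproducibility.
#'
#' @param analysis An `lt_analysis` object.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed to record in the header.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(analysis, out_dir, seed = NA_integer_) {
  stopifnot(inherits(analysis, "lt_analysis"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(df, p, na = "")
    paths <<- c(paths, p)
  }
  put(tibble(
    key = c("seed", "ctdna_threshold", "tissue_threshold", "n_patients"),
    value = c(seed, analysis$ctdna_threshold, analysis$tissue_threshold, analysis$orr$n)
  ), "report_header")
  put(analysis$orr, "orr")
  put(glance(analysis$km_pfs), "km_pfs")
  put(glance(analysis$km_os), "km_os")
  if (!is.null(analysis$roc_apcn)) put(tidy(analysis$roc_apcn), "roc_apcn_points")
  roc_sum <- purrr::map_dfr(
    c(apcn = "roc_apcn", pcn = "roc_pcn", tissue_cn = "roc_tissue"),
    function(el) if (is.null(analysis[[el]])) tibble() else glance(analysis[[el]]),
    .id = "score"
  )
  if (nrow(roc_sum)) put(roc_sum, "roc_summary")
  if (!is.null(analysis$hr_favorable)) {
    put(bind_rows(
      mutate(analysis$hr_favorable, endpoint = "pfs"),
      mutate(analysis$hr_favorable_os, endpoint = "os")
    ), "favorable_hr")
  }
  put(analysis$change_summary, "change_by_response")
  if (!is.null(analysis$hr_decreased)) put(analysis$hr_decreased, "ctdna_change_hr")
  if (nrow(analysis$resistance)) {
    put(analysis$resistance, "resistance_report")
    put(analysis$resistance_summary, "resistance_summary")
  }
  invisible(paths)
}
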