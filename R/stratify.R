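#' Detect concurrent RTK/RAS/PI3K pathway alterations
#'
#' Screens baseline genotyping for alterations that co-occur with the HER2
#' amplification selection biomarker and predict primary resistance to dual
#' HER2 blockade. For ctDNA samples, counted events are amplifications of
#' pathway genes plus *clonal* sequence-level alterations (subclonal
#' mutations, relative clonality < 0.3, are ignored as likely passengers of
#' minor clones). Tissue NGS reports no clonality, so any sequence-level
#' pathway alteration counts there. ERBB2 amplification itself is never
#' counted -- it is the selection biomarker -- but ERBB2 point mutations are.
#'
#' @param variants Variant table; clonality columns are computed on the fly
#'   when absent (via [classify_clonality()]).
#' @param gene_set Character vector of pathway gene symbols. Default
#'   [rtk_ras_pi3k_genes()].
#' @param timepoint Which sample timepoint to screen. Default `"baseline"`.
#' @return Tibble of the qualifying variant rows (possibly empty), with
#'   clonality columns attached for plasma rows.
#' @export
detect_concurrent_alterations <- function(variants,
                                          gene_set = rtk_ras_pi3k_genes(),
                                          timepoint = "baseline") {
  if (!"clonality" %in% names(variants)) {
    variants <- classify_clonality(variants)
  }
  variants %>%
    filter(
      .data$timepoint == .env$timepoint,
      .data$gene %in% gene_set,
      # the selection biomarker is excluded in any modality
      !(.data$gene == "ERBB2" & .data$alteration_type == "amplification"),
      .data$alteration_type == "amplification" |
        (.data$sample_type == "tissue") |
        (.data$sample_type == "plasma" & .data$clonality %in% "clonal")
    )
}

#' Per-patient baseline biomarker status
#'
#' Assembles, for one modality, the two baseline factors the stratification
#' uses: the HER2 copy-number value (tissue NGS CN for tissue, ApCN for
#' ctDNA) and the presence of concurrent RTK/RAS/PI3K alterations.
#'
#' @param variants Variant table containing baseline samples.
#' @param modality `"tissue"` or `"ctdna"`.
#' @param gene_set Pathway gene set for the co-alteration screen.
#' @return Tibble with one row per patient having a baseline HER2
#'   amplification call in that modality: `patient_id`, `modality`,
#'   `her2_cn_value`, `n_concurrent`, `has_concurrent`.
#' @export
biomarker_status <- function(variants, modality = c("ctdna", "tissue"),
                             gene_set = rtk_ras_pi3k_genes()) {
  modality <- match.arg(modality)
  if (modality == "ctdna") {
    cn <- adjusted_copy_number(variants) %>%
      filter(.data$timepoint == "baseline", .data$gene == "ERBB2") %>%
      select("patient_id", her2_cn_value = "apcn")
    co <- detect_concurrent_alterations(variants, gene_set) %>%
      filter(.data$sample_type == "plasma")
  } else {
    cn <- variants %>%
      filter(
        .data$sample_type == "tissue", .data$timepoint == "baseline",
        .data$gene == "ERBB2", .data$alteration_type == "amplification"
      ) %>%
      select("patient_id", her2_cn_value = "tissue_cn")
    co <- detect_concurrent_alterations(variants, gene_set) %>%
      filter(.data$sample_type == "tissue")
  }
  co_n <- co %>%
    group_by(.data$patient_id) %>%
    summarise(n_concurrent = dplyr::n(), .groups = "drop")
  cn %>%
    distinct(.data$patient_id, .keep_all = TRUE) %>%
    left_join(co_n, by = "patient_id") %>%
    mutate(
      modality = .env$modality,
      n_concurrent = ifelse(is.na(.data$n_concurrent), 0L, .data$n_concurrent),
      has_concurrent = .data$n_concurrent > 0
    ) %>%
    select("patient_id", "modality", "her2_cn_value", "n_concurrent", "has_concurrent")
}

#' Favorable-factor classification
#'
#' A patient is "favorable" when the HER2 copy-number value meets or exceeds
#' the modality threshold (inclusive) *and* no concurrent RTK/RAS/PI3K
#' alteration is present. In the source trial the thresholds were selected by
#' ROC analysis per modality (tissue NGS CN and ApCN scales differ); pass the
#' threshold for the modality of `status`.
#'
#' @param status Output of [biomarker_status()] (columns `her2_cn_value`,
#'   `has_concurrent`).
#' @param threshold Copy-number threshold (inclusive).
#' @return `status` with a logical `favorable` column appended.
#' @export
classify_favorable <- function(status, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (any(is.na(status$her2_cn_value))) {
    abort("her2_cn_value is missing for some patients; favorable status undefined")
  }
  mutate(status,
    favorable = .data$her2_cn_value >= threshold & !.data$has_concurrent
  )
}

#' Rank-based AUROC
#'
#' Area under the receiver operating characteristic curve, computed as the
#' rank statistic `P(score_pos > score_neg) + 0.5 * P(tie)` -- identical to
#' the Mann-Whitney U statistic divided by `n1 * n2`.
#'
#' @param scores Numeric biomarker values.
#' @param labels Logical (or 0/1) outcome, `TRUE` = positive class.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(1, 3, 2, 4), c(FALSE, FALSE, TRUE, TRUE)) # 0.75
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)), !any(is.na(labels)))
  n1 <- sum(labels)
  n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) abort("both classes must be present to compute AUROC")
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  u / (n1 * n2)
}

#' @describeIn auroc Two-sided p-value for AUROC != 0.5 via the
#'   normal-approximated Mann-Whitney statistic with tie correction.
#' @export
auroc_pvalue <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) abort("both classes must be present")
  n <- n1 + n2
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1) # all scores identical
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

#' ROC analysis of a biomarker against a binary outcome
#'
#' Builds the full set of operating points (one per candidate threshold, with
#' score >= threshold called positive), the rank-based AUROC, its
#' Mann-Whitney p-value and the Youden-optimal threshold.
#'
#' @inheritParams auroc
#' @return Object of class `lt_roc`: list with `operating_points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`, sorted by
#'   threshold), `auroc`, `p_value`, `chosen_threshold`, `n_pos`, `n_neg`.
#'   Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  a <- auroc(scores, labels) # validates classes
  thr <- sort(unique(scores))
  pts <- tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels] >= t), 0),
    specificity = vapply(thr, function(t) mean(scores[!labels] < t), 0)
  ) %>%
    mutate(youden_j = .data$sensitivity + .data$specificity - 1)
  chosen <- if (length(thr) > 1) {
    # ties in J broken toward the larger (more specific) threshold
    max(pts$threshold[pts$youden_j == max(pts$youden_j)])
  } else {
    NA_real_
  }
  structure(
    list(
      operating_points = pts,
      auroc = a,
      p_value = auroc_pvalue(scores, labels),
      chosen_threshold = chosen,
      n_pos = sum(labels),
      n_neg = sum(!labels)
    ),
    class = "lt_roc"
  )
}

#' Youden-optimal threshold of an ROC analysis
#'
#' Returns the threshold maximising Youden's J = sensitivity + specificity - 1,
#' ties broken toward the larger threshold. Errors when the scores are all
#' equal (no threshold separates anything).
#'
#' @param roc An `lt_roc` object from [roc_curve()].
#' @return Scalar threshold on the score scale.
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "lt_roc"))
  if (is.na(roc$chosen_threshold)) {
    abort("all scores are equal: no threshold can be selected")
  }
  roc$chosen_threshold
}

#' @export
print.lt_roc <- function(x, ...) {
  cat(sprintf(
    "ROC analysis: %d positive / %d negative\n  AUROC = %.3f (two-sided P = %.4g)\n  Youden threshold = %s\n",
    x$n_pos, x$n_neg, x$auroc, x$p_value,
    ifelse(is.na(x$chosen_threshold), "undefined", format(x$chosen_threshold))
  ))
  invisible(x)
}

#' Compare two independent proportions (Fisher's exact test)
#'
#' Two-sided Fisher's exact p-value on the 2x2 table
#' `rbind(c(x1, n1 - x1), c(x2, n2 - x2))`, summing point probabilities no
#' larger than the observed table's.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return Tibble with `p_value`, `odds_ratio`, `prop1`, `prop2`.
#' @seealso [compare_paired_proportions()] when the two classifications are
#'   made on the same subjects.
#' @export
compare_proportions <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  ft <- fisher.test(tab)
  tibble(
    p_value = ft$p.value, odds_ratio = unname(ft$estimate),
    prop1 = x1 / n1, prop2 = x2 / n2
  )
}

#' @describeIn compare_proportions Exact McNemar test for paired
#'   classifications: `b` and `c` are the discordant-pair counts; the p-value
#'   is the two-sided exact binomial test of `b` against `Binom(b + c, 1/2)`.
#' @param b,c Discordant-pair counts (positive under one classification only).
#' @export
compare_paired_proportions <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    return(tibble(p_value = 1, b = b, c = c))
  }
  bt <- stats::binom.test(b, b + c, p = 0.5)
  tibble(p_value = bt$p.value, b = b, c = c)
}
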