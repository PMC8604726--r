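#' Maximum somatic VAF of a plasma sample
#'
#' The ctDNA fraction of a plasma sample is estimated from its maximum somatic
#' variant allele fraction (VAF) across sequence-level calls (SNVs, indels and
#' fusions). Amplifications carry no VAF and are ignored. A sample with no
#' sequence-level somatic call has an *undefined* ctDNA fraction -- that is a
#' distinct biological state (no detectable tumor shedding), not zero -- so
#' this function errors rather than returning 0.
#'
#' @param variants Data frame of variant calls for a single sample, with at
#'   least columns `alteration_type` and `vaf_percent`.
#' @return Maximum `vaf_percent` (scalar, percent units).
#' @seealso [ctdna_fraction()] for the vectorised per-sample table version,
#'   which returns `NA` instead of erroring.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   alteration_type = c("SNV", "SNV", "amplification"),
#'   vaf_percent = c(0.5, 10, NA)
#' )
#' max_somatic_vaf(calls) # 10
max_somatic_vaf <- function(variants) {
  stopifnot(is.data.frame(variants))
  vafs <- variants$vaf_percent[variants$alteration_type %in% SEQ_TYPES]
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) == 0) {
    abort("no sequence-level somatic call: ctDNA fraction is undefined, not zero",
      class = "liquidtrial_no_somatic_variants"
    )
  }
  max(vafs)
}

#' Tumor fraction from the maximum somatic VAF
#'
#' Under a diploid, heterozygous-clonal assumption the tumor (ctDNA) fraction
#' of cell-free DNA is twice the maximum somatic VAF:
#' `T = 2 * max_vaf_percent / 100`. VAFs above 50% (possible under loss of
#' heterozygosity or aneuploidy, where the assumption breaks) would give
#' T > 1; these are capped at 1.
#'
#' @param max_vaf_percent Numeric vector of maximum somatic VAFs in percent
#'   (0-100).
#' @return Numeric vector of tumor fractions in \[0, 1\]. Inputs above 50%
#'   cap at 1; use [tumor_fraction_capped()] to flag them.
#' @export
#' @examples
#' tumor_fraction(c(10, 50, 80)) # 0.2, 1.0, 1.0 (last one capped)
tumor_fraction <- function(max_vaf_percent) {
  if (any(max_vaf_percent < 0 | max_vaf_percent > 100, na.rm = TRUE)) {
    abort("max_vaf_percent must be in [0, 100]")
  }
  pmin(2 * max_vaf_percent / 100, 1)
}

#' @rdname tumor_fraction
#' @export
tumor_fraction_capped <- function(max_vaf_percent) {
  !is.na(max_vaf_percent) & max_vaf_percent > 50
}

#' Tumor-fraction-adjusted plasma copy number (ApCN)
#'
#' The copy number observed in cell-free DNA is a mixture of tumor-derived
#' signal and normal diploid background: `pCN = T * CN_tumor + 2 * (1 - T)`.
#' Inverting this gives the tumor-level estimate
#' `ApCN = (pCN - 2 * (1 - T)) / T`, which removes the confounding effect of
#' how much ctDNA the tumor sheds. At `T = 1` the adjustment is the identity,
#' and a copy-neutral gene (`pCN = 2`) maps to ApCN 2 at any tumor fraction.
#'
#' Assay noise at low tumor fraction can push the raw adjusted value below 0;
#' the raw value is kept in `apcn_raw` and clipped to 0 in `apcn` for
#' downstream threshold classification, with `flag = "clipped_negative"`.
#' A tumor fraction of exactly 0 makes the adjustment impossible and errors.
#'
#' @param observed_pcn Numeric vector of observed plasma copy numbers
#'   (copies, >= 0).
#' @param tf Numeric vector of tumor fractions in (0, 1\], recycled
#'   against `observed_pcn`.
#' @return Tibble with columns `observed_pcn`, `tumor_fraction`, `apcn_raw`,
#'   `apcn` (clipped at 0) and `flag` (`"ok"` or `"clipped_negative"`).
#' @export
#' @examples
#' adjust_plasma_cn(8.6, 1)       # identity at full tumor fraction
#' adjust_plasma_cn(2, 0.4)       # copy-neutral fixed point: ApCN = 2
#' adjust_plasma_cn(4.45, 0.1)    # low shedder: 4.45 copies in plasma is 26.5 in tumor
adjust_plasma_cn <- function(observed_pcn, tf) {
  n <- max(length(observed_pcn), length(tf))
  observed_pcn <- rep_len(observed_pcn, n)
  tf <- rep_len(tf, n)
  if (any(observed_pcn < 0, na.rm = TRUE)) abort("observed_pcn must be >= 0")
  if (any(tf == 0, na.rm = TRUE)) {
    abort("tumor fraction is 0: adjusted copy number is undefined",
      class = "liquidtrial_zero_tumor_fraction"
    )
  }
  if (any(tf < 0 | tf > 1, na.rm = TRUE)) abort("tumor fraction must be in (0, 1]")
  # algebraically identical to (pCN - 2*(1 - T)) / T but exact at the
  # copy-neutral fixed point pCN = 2 and at T = 1
  raw <- (observed_pcn - 2) / tf + 2
  tibble(
    observed_pcn = observed_pcn,
    tumor_fraction = tf,
    apcn_raw = raw,
    apcn = pmax(raw, 0),
    flag = ifelse(!is.na(raw) & raw < 0, "clipped_negative", "ok")
  )
}

#' Per-sample ctDNA fraction table
#'
#' Computes, for every plasma sample (patient x timepoint) in a variant table,
#' the maximum somatic VAF, the tumor fraction and a capping flag. Samples
#' whose only calls are amplifications get `NA` metrics with
#' `flag = "no_somatic_snv"` (ctDNA fraction undefined); samples absent from
#' the table do not appear.
#'
#' @param variants Variant table (see [read_variant_table()] for the schema);
#'   tissue rows are ignored.
#' @return Tibble with one row per plasma sample: `patient_id`, `timepoint`,
#'   `n_calls`, `max_vaf_percent`, `tumor_fraction`, `flag`
#'   (`"ok"`, `"fraction_capped"` or `"no_somatic_snv"`).
#' @export
ctdna_fraction <- function(variants) {
  variants %>%
    filter(.data$sample_type == "plasma") %>%
    group_by(.data$patient_id, .data$timepoint) %>%
    summarise(
      n_calls = dplyr::n(),
      max_vaf_percent = {
        v <- .data$vaf_percent[.data$alteration_type %in% SEQ_TYPES]
        v <- v[!is.na(v)]
        if (length(v)) max(v) else NA_real_
      },
      .groups = "drop"
    ) %>%
    mutate(
      tumor_fraction = ifelse(is.na(.data$max_vaf_percent), NA_real_,
        tumor_fraction(ifelse(is.na(.data$max_vaf_percent), 0, .data$max_vaf_percent))
      ),
      flag = case_when(
        is.na(.data$max_vaf_percent) ~ "no_somatic_snv",
        tumor_fraction_capped(.data$max_vaf_percent) ~ "fraction_capped",
        TRUE ~ "ok"
      )
    )
}

#' Clonality classification of sequence-level calls
#'
#' Each SNV/indel/fusion call in a plasma sample gets a relative clonality:
#' its VAF divided by the sample's maximum somatic VAF. Calls with relative
#' clonality strictly below 0.3 are labelled subclonal; exactly 0.3 is clonal.
#' The call(s) attaining the maximum VAF have relative clonality 1.
#' Amplifications carry no VAF, receive `NA` clonality, and are treated as
#' clonal events by downstream co-alteration screening.
#'
#' @param variants Variant table; tissue rows pass through with `NA` clonality.
#' @param subclonal_below Relative-clonality cutoff; strictly below it is
#'   subclonal. Default 0.3.
#' @return The input with columns `relative_clonality` and `clonality`
#'   (`"clonal"` / `"subclonal"`, `NA` for amplifications and tissue rows)
#'   appended.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   patient_id = "P1", sample_type = "plasma", timepoint = "baseline",
#'   gene = c("TP53", "KRAS"), alteration_type = "SNV",
#'   vaf_percent = c(10, 2.9)
#' )
#' classify_clonality(calls) # KRAS at 0.29 is subclonal
classify_clonality <- function(variants, subclonal_below = 0.3) {
  variants %>%
    group_by(.data$patient_id, .data$sample_type, .data$timepoint) %>%
    mutate(
      relative_clonality = {
        seq_call <- .data$alteration_type %in% SEQ_TYPES &
          .data$sample_type == "plasma" & !is.na(.data$vaf_percent)
        mv <- if (any(seq_call)) max(.data$vaf_percent[seq_call]) else NA_real_
        ifelse(seq_call, .data$vaf_percent / mv, NA_real_)
      },
      clonality = case_when(
        is.na(.data$relative_clonality) ~ NA_character_,
        .data$relative_clonality < subclonal_below ~ "subclonal",
        TRUE ~ "clonal"
      )
    ) %>%
    ungroup()
}

#' Adjusted copy number for every plasma amplification call
#'
#' Joins each plasma amplification call with its sample's tumor fraction
#' (from [ctdna_fraction()]) and computes the tumor-fraction-adjusted plasma
#' copy number. Amplifications in samples without any sequence-level call
#' cannot be adjusted and get `flag = "undefined_zero_fraction"` with `NA`
#' ApCN.
#'
#' @inheritParams ctdna_fraction
#' @return Tibble with one row per plasma amplification call: `patient_id`,
#'   `timepoint`, `gene`, `observed_pcn`, `tumor_fraction`, `apcn_raw`,
#'   `apcn`, `flag`.
#' @export
adjusted_copy_number <- function(variants) {
  fr <- ctdna_fraction(variants)
  amps <- variants %>%
    filter(.data$sample_type == "plasma", .data$alteration_type == "amplification") %>%
    select("patient_id", "timepoint", "gene", observed_pcn = "plasma_cn") %>%
    left_join(
      select(fr, "patient_id", "timepoint", "tumor_fraction", sample_flag = "flag"),
      by = c("patient_id", "timepoint")
    )
  ok <- !is.na(amps$tumor_fraction) & amps$tumor_fraction > 0
  adj <- tibble(apcn_raw = rep(NA_real_, nrow(amps)), apcn = NA_real_, flag = "undefined_zero_fraction")
  if (any(ok)) {
    a <- adjust_plasma_cn(amps$observed_pcn[ok], amps$tumor_fraction[ok])
    adj$apcn_raw[ok] <- a$apcn_raw
    adj$apcn[ok] <- a$apcn
    adj$flag[ok] <- ifelse(amps$sample_flag[ok] == "fraction_capped",
      "fraction_capped", a$flag
    )
  }
  amps %>%
    select(-"sample_flag") %>%
    mutate(apcn_raw = adj$apcn_raw, apcn = adj$apcn, flag = adj$flag)
}
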