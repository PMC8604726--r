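# Small in-code fixtures shared across test files.

# single-sample plasma variant tibble from VAFs (SNVs) and optional amps
plasma_calls <- function(vafs = numeric(), amp_genes = character(),
                         amp_pcn = numeric(), genes = NULL,
                         patient_id = "P1", timepoint = "baseline") {
  genes <- genes %||% paste0("G", seq_along(vafs))
  dplyr::bind_rows(
    if (length(vafs)) {
      tibble::tibble(
        patient_id = patient_id, sample_type = "plasma", timepoint = timepoint,
        gene = genes, alteration_type = "SNV",
        variant_label = paste0(genes, ":m1"),
        vaf_percent = vafs, plasma_cn = NA_real_
      )
    },
    if (length(amp_genes)) {
      tibble::tibble(
        patient_id = patient_id, sample_type = "plasma", timepoint = timepoint,
        gene = amp_genes, alteration_type = "amplification",
        variant_label = paste0(amp_genes, ":amp"),
        vaf_percent = NA_real_, plasma_cn = amp_pcn
      )
    }
  )
}

`%||%` <- rlang::`%||%`

# tiny deterministic cohort for pipeline tests
small_cohort <- function(seed = 42, n = 60, ...) {
  simulate_cohort(cohort_config(seed = seed, n_patients = n, ...))
}
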