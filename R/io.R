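VARIANT_COLS <- c(
  "patient_id", "sample_type", "timepoint", "gene", "alteration_type",
  "variant_label", "vaf_percent", "plasma_cn", "tissue_cn",
  "fish_ratio", "fish_cn", "ihc_score"
)
CLINICAL_COLS <- c(
  "patient_id", "tissue_positive", "ctdna_positive",
  "assessment_day", "assessment_category", "sld_change_percent",
  "pfs_months", "pfs_event", "os_months", "os_event"
)

variant_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    sample_type = readr::col_character(),
    timepoint = readr::col_character(),
    gene = readr::col_character(),
    alteration_type = readr::col_character(),
    variant_label = readr::col_character(),
    vaf_percent = readr::col_double(),
    plasma_cn = readr::col_double(),
    tissue_cn = readr::col_double(),
    fish_ratio = readr::col_double(),
    fish_cn = readr::col_double(),
    ihc_score = readr::col_character()
  )
}

fail_rows <- function(msg, rows) {
  abort(sprintf("%s (row%s %s)", msg, ifelse(length(rows) > 1, "s", ""),
    paste(utils::head(rows, 10), collapse = ", ")
  ), class = "liquidtrial_schema_error")
}

#' Validate a variant table against the schema
#'
#' Checks required columns, allowed factor levels, value ranges, the
#' VAF/copy-number mutual exclusion per call, and the modality rules: tissue
#' rows carry no `vaf_percent`/`plasma_cn`; plasma rows carry no
#' `tissue_cn`/FISH/IHC fields. Errors name the offending rows (1-based,
#' excluding the header).
#'
#' @param variants Data frame to validate.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_variant_table <- function(variants) {
  missing_cols <- setdiff(
    c("patient_id", "sample_type", "timepoint", "gene", "alteration_type"),
    names(variants)
  )
  if (length(missing_cols)) {
    abort(paste("variant table is missing columns:", paste(missing_cols, collapse = ", ")),
      class = "liquidtrial_schema_error"
    )
  }
  for (col in setdiff(VARIANT_COLS, names(variants))) {
    variants[[col]] <- if (col == "variant_label" || col == "ihc_score") NA_character_ else NA_real_
  }
  variants <- as_tibble(variants[VARIANT_COLS])
  r <- seq_len(nrow(variants))
  bad <- r[!variants$sample_type %in% c("plasma", "tissue")]
  if (length(bad)) fail_rows("sample_type must be 'plasma' or 'tissue'", bad)
  bad <- r[!variants$timepoint %in% c("baseline", "week3", "progression")]
  if (length(bad)) fail_rows("timepoint must be baseline/week3/progression", bad)
  bad <- r[!variants$alteration_type %in% ALTERATION_TYPES]
  if (length(bad)) fail_rows("unknown alteration_type", bad)
  bad <- r[!is.na(variants$vaf_percent) & (variants$vaf_percent < 0 | variants$vaf_percent > 100)]
  if (length(bad)) fail_rows("vaf_percent outside [0, 100]", bad)
  for (cn in c("plasma_cn", "tissue_cn", "fish_cn", "fish_ratio")) {
    bad <- r[!is.na(variants[[cn]]) & variants[[cn]] < 0]
    if (length(bad)) fail_rows(paste(cn, "must be >= 0"), bad)
  }
  bad <- r[!is.na(variants$vaf_percent) & !is.na(variants$plasma_cn)]
  if (length(bad)) fail_rows("vaf_percent and plasma_cn are mutually exclusive per call", bad)
  amp <- variants$alteration_type == "amplification"
  bad <- r[amp & !is.na(variants$vaf_percent)]
  if (length(bad)) fail_rows("amplification calls carry no vaf_percent", bad)
  pl <- variants$sample_type == "plasma"
  bad <- r[pl & (!is.na(variants$tissue_cn) | !is.na(variants$fish_ratio) |
    !is.na(variants$fish_cn) | !is.na(variants$ihc_score))]
  if (length(bad)) fail_rows("plasma rows carry no tissue_cn/fish/ihc fields", bad)
  bad <- r[!pl & (!is.na(variants$vaf_percent) | !is.na(variants$plasma_cn))]
  if (length(bad)) fail_rows("tissue rows carry no vaf_percent/plasma_cn", bad)
  variants
}

#' Read and write the variant TSV
#'
#' Tab-separated, UTF-8, header row, empty string = missing. One row per
#' somatic call per sample. See [validate_variant_table()] for the schema
#' rules enforced on read.
#'
#' @param path File path.
#' @return `read_variant_table()` returns the validated variant tibble.
#' @export
read_variant_table <- function(path) {
  spec <- variant_col_types()
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  spec$cols <- spec$cols[intersect(names(spec$cols), hdr)]
  v <- readr::read_tsv(path, col_types = spec, na = "", progress = FALSE)
  validate_variant_table(v)
}

#' @rdname read_variant_table
#' @param variants Variant tibble to write.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(validate_variant_table(variants), path, na = "")
  invisible(path)
}

#' Read and write the clinical TSV
#'
#' One row per response assessment; patient-level survival columns
#' (`pfs_months`, `pfs_event`, `os_months`, `os_event`) are repeated on each
#' of a patient's rows. Assessment times are in days from treatment start;
#' survival times in months (days / 30.4375).
#'
#' @param path File path.
#' @return `read_clinical_table()` returns the validated clinical tibble.
#' @export
read_clinical_table <- function(path) {
  cl <- readr::read_tsv(path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      assessment_category = readr::col_character(),
      .default = readr::col_guess()
    ), na = "", progress = FALSE
  )
  validate_clinical_table(cl)
}

#' @rdname read_clinical_table
#' @param clinical Clinical tibble to write.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(validate_clinical_table(clinical), path, na = "")
  invisible(path)
}

#' @rdname validate_variant_table
#' @param clinical Clinical data frame to validate.
#' @export
validate_clinical_table <- function(clinical) {
  missing_cols <- setdiff(CLINICAL_COLS, names(clinical))
  if (length(missing_cols)) {
    abort(paste("clinical table is missing columns:", paste(missing_cols, collapse = ", ")),
      class = "liquidtrial_schema_error"
    )
  }
  r <- seq_len(nrow(clinical))
  bad <- r[!clinical$assessment_category %in% RESPONSE_LEVELS]
  if (length(bad)) fail_rows("unknown assessment_category", bad)
  bad <- r[clinical$assessment_day < 0 | clinical$pfs_months < 0 | clinical$os_months < 0]
  if (length(bad)) fail_rows("times must be non-negative", bad)
  bad <- r[clinical$pfs_months > clinical$os_months]
  if (length(bad)) fail_rows("pfs_months must not exceed os_months", bad)
  as_tibble(clinical)
}
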