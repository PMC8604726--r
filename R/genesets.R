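#' Pathway gene sets used for co-alteration and actionability calls
#'
#' `rtk_ras_pi3k_genes()` returns the default receptor tyrosine kinase /
#' RAS-MAPK / PI3K-AKT pathway gene set used to flag concurrent resistance
#' alterations at baseline. `actionable_genes()` returns the default set used
#' to call an acquired alteration "actionable" at progression; it is the
#' RTK/RAS/PI3K set (ERBB2 amplification included, since an emergent ERBB2
#' amplification is itself a drug target).
#'
#' Both are plain character vectors of HGNC symbols so users can pass their
#' own panel-specific sets to any function that takes a `gene_set` argument.
#'
#' Note one asymmetry handled downstream, not here: when screening *baseline*
#' co-alterations, ERBB2 amplification is never counted because it is the
#' trial's selection biomarker ([detect_concurrent_alterations()] applies that
#' exclusion); ERBB2 point mutations are counted.
#'
#' @return Character vector of HGNC gene symbols.
#' @export
#' @examples
#' rtk_ras_pi3k_genes()
rtk_ras_pi3k_genes <- function() {
  c(
    "EGFR", "ERBB2", "ERBB3", "MET", "FGFR1", "FGFR2",
    "KRAS", "NRAS", "HRAS", "BRAF", "MAP2K1",
    "PIK3CA", "PTEN", "AKT1"
  )
}

#' @rdname rtk_ras_pi3k_genes
#' @export
actionable_genes <- function() {
  rtk_ras_pi3k_genes()
}

# alteration types carrying a VAF (sequence-level calls)
SEQ_TYPES <- c("SNV", "indel", "fusion")
ALTERATION_TYPES <- c(SEQ_TYPES, "amplification")
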