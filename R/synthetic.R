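#' Configuration for the synthetic longitudinal genotyping cohort
#'
#' Defines every distribution and rate the cohort generator uses. The
#' defaults describe a HER2-amplified metastatic colorectal cancer cohort
#' profiled by plasma NGS at baseline, week 3 and progression, with tissue
#' NGS at baseline, under a forward model chosen so that the
#' tumor-fraction adjustment is exactly correct in the noiseless limit:
#' `observed pCN = T * CN_true + 2 * (1 - T)`.
#'
#' Key defaults: tumor fraction log-normal with median 10%; true tumor-level
#' HER2 copy number `2 + LogNormal(log 25, 0.8)`; assay reportable ranges
#' VAF >= 0.04% and amplification >= 2.12 copies; week-3 clearance
#' multipliers 0 / 0.32 / 0.68 / 1.46 / 1.21 for CR / PR / SD-with-shrinkage /
#' SD-without-shrinkage / PD; benefit probability 0.75 above the ApCN-scale
#' copy-number threshold 16.7 (0.15 below), multiplied by 0.2 when a
#' concurrent RTK/RAS/PI3K alteration is present; exponential PFS with
#' median 5.6 / 1.6 months (benefit / no benefit) and OS 16.5 / 5.7;
#' actionable-alteration emergence probability 0.62 at progression and HER2
#' amplification loss probability 0.15.
#'
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param n_patients Cohort size.
#' @param tf_meanlog,tf_sdlog Log-normal parameters of the baseline tumor
#'   fraction (capped at 1).
#' @param cn_meanlog,cn_sdlog Log-normal parameters of the amplified part of
#'   the true tumor HER2 copy number (`CN_true = 2 + LogNormal`).
#' @param cn_noise_sdlog Multiplicative log-normal noise SD on observed
#'   plasma copy numbers; set 0 for a noiseless forward model.
#' @param tissue_noise_sdlog Multiplicative noise SD on tissue NGS copy
#'   number.
#' @param coalteration_prob Probability a patient carries a concurrent
#'   RTK/RAS/PI3K alteration.
#' @param tissue_coalt_sensitivity Probability tissue NGS detects a
#'   co-alteration the tumor carries.
#' @param cn_threshold ApCN-scale copy-number threshold of the benefit model.
#' @param baseline_benefit_prob,low_cn_benefit_prob Benefit probability for
#'   patients above/below `cn_threshold`.
#' @param coalteration_penalty Multiplier on the benefit probability when a
#'   co-alteration is present.
#' @param clearance_mult Named multipliers (CR, PR, SD_shrinkage,
#'   SD_no_shrinkage, PD) for the week-3/baseline ctDNA-fraction ratio.
#' @param clearance_sdlog Log-normal spread around the clearance multipliers.
#' @param pfs_median_benefit,pfs_median_no_benefit,os_median_benefit,os_median_no_benefit
#'   Exponential survival medians in months by benefit stratum.
#' @param week3_collected_prob,progression_sample_prob Sample-collection
#'   probabilities for the week-3 draw and (among progressors) the
#'   progression draw.
#' @param emergence_prob Probability an actionable alteration emerges at
#'   progression.
#' @param her2_loss_prob Probability the HER2 amplification call is lost at
#'   progression.
#' @param detection_min_vaf,detection_min_pcn Assay reportable ranges:
#'   minimum emitted VAF (percent) and amplification plasma copy number.
#' @return List of class `lt_cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_patients = 500L,
                          tf_meanlog = log(0.10), tf_sdlog = 1.0,
                          cn_meanlog = log(25), cn_sdlog = 0.8,
                          cn_noise_sdlog = 0.10,
                          tissue_noise_sdlog = 0.15,
                          coalteration_prob = 0.45,
                          tissue_coalt_sensitivity = 0.30,
                          cn_threshold = 16.7,
                          baseline_benefit_prob = 0.75,
                          low_cn_benefit_prob = 0.15,
                          coalteration_penalty = 0.20,
                          clearance_mult = c(
                            CR = 0, PR = 0.32, SD_shrinkage = 0.68,
                            SD_no_shrinkage = 1.46, PD = 1.21
                          ),
                          clearance_sdlog = 0.35,
                          pfs_median_benefit = 5.6,
                          pfs_median_no_benefit = 1.6,
                          os_median_benefit = 16.5,
                          os_median_no_benefit = 5.7,
                          week3_collected_prob = 0.93,
                          progression_sample_prob = 0.90,
                          emergence_prob = 0.62,
                          her2_loss_prob = 0.15,
                          detection_min_vaf = 0.04,
                          detection_min_pcn = 2.12) {
  cfg <- as.list(environment())
  probs <- c(
    cfg$coalteration_prob, cfg$tissue_coalt_sensitivity,
    cfg$baseline_benefit_prob, cfg$low_cn_benefit_prob, cfg$coalteration_penalty,
    cfg$week3_collected_prob, cfg$progression_sample_prob,
    cfg$emergence_prob, cfg$her2_loss_prob
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$detection_min_vaf <= 0 || cfg$detection_min_pcn <= 0) {
    abort("detection limits must be positive")
  }
  if (!all(c("CR", "PR", "SD_shrinkage", "SD_no_shrinkage", "PD") %in%
    names(cfg$clearance_mult))) {
    abort("clearance_mult must name CR, PR, SD_shrinkage, SD_no_shrinkage, PD")
  }
  if (cfg$n_patients < 1) abort("n_patients must be >= 1")
  structure(cfg, class = "lt_cohort_config")
}

PASSENGER_GENES <- c("APC", "SMAD4", "ARID1A", "FBXW7", "TCF7L2", "SOX9", "ATM")

# exponential draw with given median, optionally truncated below/above
rexp_median <- function(n, median, lower = 0, upper = Inf) {
  rate <- log(2) / median
  plo <- stats::pexp(lower, rate)
  phi <- stats::pexp(upper, rate)
  stats::qexp(plo + runif(n) * (phi - plo), rate)
}

variant_row <- function(patient_id, sample_type, timepoint, gene, type,
                        label = NA_character_, vaf = NA_real_, pcn = NA_real_,
                        tcn = NA_real_, fish_ratio = NA_real_,
                        fish_cn = NA_real_, ihc = NA_character_) {
  vaf <- pmin(vaf, 100) # allele fractions are bounded above by 100%
  # a plain named list keeps per-row construction cheap; rows are bound once
  list(
    patient_id = patient_id, sample_type = sample_type, timepoint = timepoint,
    gene = gene, alteration_type = type, variant_label = label,
    vaf_percent = vaf, plasma_cn = pcn, tissue_cn = tcn,
    fish_ratio = fish_ratio, fish_cn = fish_cn, ihc_score = ihc
  )
}

observed_pcn_fwd <- function(cn_true, tf, noise_sdlog) {
  (tf * cn_true + 2 * (1 - tf)) * exp(rnorm(length(cn_true), 0, noise_sdlog))
}

simulate_patient <- function(cfg, i) {
  pid <- sprintf("P%04d", i)
  # per-patient substream: adding patients never reshuffles earlier ones
  set.seed(as.integer((cfg$seed * 1009 + i * 7919) %% 2147483647) + 1L)

  tf <- min(rlnorm(1, cfg$tf_meanlog, cfg$tf_sdlog), 1)
  cn_true <- 2 + rlnorm(1, cfg$cn_meanlog, cfg$cn_sdlog)
  max_vaf <- 50 * tf # diploid heterozygous-clonal driver

  vrows <- list()
  add <- function(row) vrows[[length(vrows) + 1]] <<- row

  # --- baseline plasma ---
  seq_calls <- tibble(
    gene = "TP53", label = "TP53:c1", vaf = max_vaf, source = "driver"
  )
  k <- stats::rpois(1, 2)
  if (k > 0) {
    k <- min(k, length(PASSENGER_GENES))
    pg <- sample(PASSENGER_GENES, k)
    seq_calls <- bind_rows(seq_calls, tibble(
      gene = pg, label = paste0(pg, ":p1"),
      vaf = max_vaf * runif(k, 0.05, 1), source = "passenger"
    ))
  }
  has_coalt <- runif(1) < cfg$coalteration_prob
  coalt <- NULL
  if (has_coalt) {
    cg <- sample(setdiff(rtk_ras_pi3k_genes(), "ERBB2"), 1)
    if (runif(1) < 0.7) {
      coalt <- list(gene = cg, type = "SNV", label = paste0(cg, ":r1"),
                    vaf = max_vaf * runif(1, 0.35, 1), cn_true = NA_real_)
    } else {
      coalt <- list(gene = cg, type = "amplification", label = paste0(cg, ":r1"),
                    vaf = NA_real_, cn_true = 2 + rlnorm(1, log(6), 0.5))
    }
  }
  for (j in seq_len(nrow(seq_calls))) {
    if (seq_calls$vaf[j] >= cfg$detection_min_vaf) {
      add(variant_row(pid, "plasma", "baseline", seq_calls$gene[j], "SNV",
        label = seq_calls$label[j], vaf = seq_calls$vaf[j]
      ))
    }
  }
  her2_pcn <- observed_pcn_fwd(cn_true, tf, cfg$cn_noise_sdlog)
  if (her2_pcn >= cfg$detection_min_pcn) {
    add(variant_row(pid, "plasma", "baseline", "ERBB2", "amplification",
      label = "ERBB2:amp", pcn = her2_pcn
    ))
  }
  if (has_coalt) {
    if (coalt$type == "SNV") {
      if (coalt$vaf >= cfg$detection_min_vaf) {
        add(variant_row(pid, "plasma", "baseline", coalt$gene, "SNV",
          label = coalt$label, vaf = coalt$vaf
        ))
      }
    } else {
      cpcn <- observed_pcn_fwd(coalt$cn_true, tf, cfg$cn_noise_sdlog)
      if (cpcn >= cfg$detection_min_pcn) {
        add(variant_row(pid, "plasma", "baseline", coalt$gene, "amplification",
          label = coalt$label, pcn = cpcn
        ))
      }
    }
  }

  # --- baseline tissue ---
  tissue_cn <- cn_true * exp(rnorm(1, 0, cfg$tissue_noise_sdlog))
  add(variant_row(pid, "tissue", "baseline", "ERBB2", "amplification",
    label = "ERBB2:amp", tcn = tissue_cn,
    fish_ratio = pmax(cn_true / 2 * exp(rnorm(1, 0, 0.3)), 1),
    fish_cn = cn_true * exp(rnorm(1, 0, 0.3)), ihc = "3+"
  ))
  if (has_coalt && runif(1) < cfg$tissue_coalt_sensitivity) {
    if (coalt$type == "SNV") {
      add(variant_row(pid, "tissue", "baseline", coalt$gene, "SNV",
        label = coalt$label
      ))
    } else {
      add(variant_row(pid, "tissue", "baseline", coalt$gene, "amplification",
        label = coalt$label,
        tcn = coalt$cn_true * exp(rnorm(1, 0, cfg$tissue_noise_sdlog))
      ))
    }
  }

  # --- outcome model ---
  p_benefit <- ifelse(cn_true >= cfg$cn_threshold,
    cfg$baseline_benefit_prob, cfg$low_cn_benefit_prob
  )
  if (has_coalt) p_benefit <- p_benefit * cfg$coalteration_penalty
  benefit <- runif(1) < p_benefit
  if (benefit) {
    category <- sample(c("CR", "PR", "SD"), 1, prob = c(0.10, 0.60, 0.30))
    shrink <- category == "SD" && runif(1) < 0.65
  } else {
    category <- sample(c("SD", "PD"), 1, prob = c(0.35, 0.65))
    shrink <- category == "SD" && runif(1) < 0.25
  }
  group5 <- if (category == "SD") {
    if (shrink) "SD_shrinkage" else "SD_no_shrinkage"
  } else {
    category
  }
  sld <- switch(group5,
    CR = -100,
    PR = runif(1, -85, -30),
    SD_shrinkage = runif(1, -25, -1),
    SD_no_shrinkage = runif(1, 0, 15),
    PD = runif(1, 20, 60)
  )
  pfs_med <- ifelse(benefit, cfg$pfs_median_benefit, cfg$pfs_median_no_benefit)
  pfs <- if (benefit && category == "SD") {
    rexp_median(1, pfs_med, lower = 4.0) # benefit SD lasts >= 4 months
  } else if (benefit) {
    rexp_median(1, pfs_med, lower = 84 / DAYS_PER_MONTH) # response held >= confirmation scan
  } else if (category == "SD") {
    rexp_median(1, pfs_med, upper = 4.0)
  } else {
    rexp_median(1, pfs_med)
  }
  pfs_event <- pfs <= 24
  pfs_months <- min(pfs, 24)
  os_extra_med <- ifelse(benefit,
    cfg$os_median_benefit - cfg$pfs_median_benefit,
    cfg$os_median_no_benefit - cfg$pfs_median_no_benefit
  )
  os <- pfs_months + rexp_median(1, os_extra_med)
  os_event <- os <= 36
  os_months <- min(os, 36)

  # --- assessment series ---
  assess <- switch(category,
    CR = tibble(day = c(42, 84), category = "CR", sld = sld),
    PR = tibble(day = c(42, 84), category = "PR", sld = sld),
    SD = {
      d <- c(42, if (pfs_months * DAYS_PER_MONTH > 84) 84)
      tibble(day = d, category = "SD", sld = sld)
    },
    PD = tibble(day = 42, category = "PD", sld = sld)
  )
  pfs_day <- round(pfs_months * DAYS_PER_MONTH)
  if (pfs_event && category != "PD" && pfs_day > max(assess$day)) {
    assess <- bind_rows(assess, tibble(day = pfs_day, category = "PD", sld = max(sld + 30, 20)))
  }

  # --- week-3 plasma ---
  week3_collected <- runif(1) < cfg$week3_collected_prob
  if (week3_collected) {
    mult <- unname(cfg$clearance_mult[group5])
    ratio <- if (mult == 0) 0 else mult * exp(rnorm(1, 0, cfg$clearance_sdlog))
    if (ratio > 0) {
      w_vafs <- seq_calls$vaf * ratio
      if (has_coalt && coalt$type == "SNV") {
        w_vafs <- c(w_vafs, coalt$vaf * ratio)
        w_genes <- c(seq_calls$gene, coalt$gene)
        w_labels <- c(seq_calls$label, coalt$label)
      } else {
        w_genes <- seq_calls$gene
        w_labels <- seq_calls$label
      }
      tf3 <- min(tf * ratio, 1)
      for (j in seq_along(w_vafs)) {
        if (w_vafs[j] >= cfg$detection_min_vaf) {
          add(variant_row(pid, "plasma", "week3", w_genes[j], "SNV",
            label = w_labels[j], vaf = w_vafs[j]
          ))
        }
      }
      p3 <- observed_pcn_fwd(cn_true, tf3, cfg$cn_noise_sdlog)
      if (any(w_vafs >= cfg$detection_min_vaf) && p3 >= cfg$detection_min_pcn) {
        add(variant_row(pid, "plasma", "week3", "ERBB2", "amplification",
          label = "ERBB2:amp", pcn = p3
        ))
      }
    }
  }

  # --- progression plasma ---
  progression_collected <- pfs_event && runif(1) < cfg$progression_sample_prob
  if (progression_collected) {
    rebound <- exp(rnorm(nrow(seq_calls), 0, 0.3))
    for (j in seq_len(nrow(seq_calls))) {
      v <- seq_calls$vaf[j] * rebound[j]
      if (v >= cfg$detection_min_vaf) {
        add(variant_row(pid, "plasma", "progression", seq_calls$gene[j], "SNV",
          label = seq_calls$label[j], vaf = v
        ))
      }
    }
    if (has_coalt) {
      if (coalt$type == "SNV") {
        v <- coalt$vaf * exp(rnorm(1, 0, 0.3))
        if (v >= cfg$detection_min_vaf) {
          add(variant_row(pid, "plasma", "progression", coalt$gene, "SNV",
            label = coalt$label, vaf = v
          ))
        }
      } else {
        cp <- observed_pcn_fwd(coalt$cn_true, tf, cfg$cn_noise_sdlog)
        if (cp >= cfg$detection_min_pcn) {
          add(variant_row(pid, "plasma", "progression", coalt$gene, "amplification",
            label = coalt$label, pcn = cp
          ))
        }
      }
    }
    her2_lost <- runif(1) < cfg$her2_loss_prob
    if (!her2_lost) {
      pp <- observed_pcn_fwd(cn_true, tf, cfg$cn_noise_sdlog)
      if (pp >= cfg$detection_min_pcn) {
        add(variant_row(pid, "plasma", "progression", "ERBB2", "amplification",
          label = "ERBB2:amp", pcn = pp
        ))
      }
    }
    if (runif(1) < cfg$emergence_prob) {
      existing <- c(seq_calls$gene, if (has_coalt) coalt$gene)
      eg <- sample(setdiff(actionable_genes(), existing), 1)
      if (runif(1) < 0.8) {
        ev <- max_vaf * runif(1, 0.3, 1)
        if (ev >= cfg$detection_min_vaf) {
          add(variant_row(pid, "plasma", "progression", eg, "SNV",
            label = paste0(eg, ":e1"), vaf = ev
          ))
        }
      } else {
        ecn <- observed_pcn_fwd(2 + rlnorm(1, log(6), 0.5), tf, cfg$cn_noise_sdlog)
        if (ecn >= cfg$detection_min_pcn) {
          add(variant_row(pid, "plasma", "progression", eg, "amplification",
            label = paste0(eg, ":e1"), pcn = ecn
          ))
        }
      }
    }
  }

  clinical <- tibble(
    patient_id = pid,
    tissue_positive = TRUE, ctdna_positive = TRUE,
    assessment_day = assess$day,
    assessment_category = assess$category,
    sld_change_percent = assess$sld,
    pfs_months = pfs_months, pfs_event = pfs_event,
    os_months = os_months, os_event = os_event,
    week3_collected = week3_collected,
    progression_collected = progression_collected
  )
  truth <- tibble(
    patient_id = pid, tumor_fraction_true = tf, her2_cn_true = cn_true,
    has_coalteration = has_coalt, benefit_true = benefit,
    response_group = group5
  )
  list(variants = bind_rows(vrows), clinical = clinical, truth = truth)
}

#' Generate a synthetic longitudinal genotyping cohort
#'
#' Draws, for each patient, a true tumor-level HER2 copy number and tumor
#' fraction; emits baseline plasma calls (clonal driver SNV whose VAF fixes
#' the tumor fraction, passenger SNVs, the HER2 amplification with
#' `observed pCN = T * CN_true + 2 * (1 - T)` plus multiplicative noise,
#' and optionally a concurrent RTK/RAS/PI3K alteration), a baseline tissue
#' profile, a week-3 plasma profile whose ctDNA fraction is scaled by a
#' response-dependent clearance multiplier, and a progression profile with
#' possible emergent actionable alterations and HER2 amplification loss.
#' Calls below the configured reportable ranges are dropped. Outcomes
#' (response category, confirmation series, SLD change, exponential PFS/OS)
#' depend on the true copy number and co-alteration status through the
#' benefit model, so favorable-factor stratification has signal to recover.
#'
#' Each patient uses a deterministic seed substream derived from the config
#' seed, so the same patient is identical across cohort sizes and the whole
#' cohort is byte-reproducible.
#'
#' @param config An [cohort_config()] object.
#' @return List with `variants` (variant table), `clinical` (per-assessment
#'   clinical table) and `truth` (per-patient latent values: true tumor
#'   fraction, true HER2 CN, co-alteration, benefit stratum, response group)
#'   for generator-level validation.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7, n_patients = 20))
#' dplyr::count(coh$variants, sample_type, timepoint)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "lt_cohort_config"))
  out <- purrr::map(seq_len(config$n_patients), ~ simulate_patient(config, .x))
  list(
    variants = purrr::map_dfr(out, "variants"),
    clinical = purrr::map_dfr(out, "clinical"),
    truth = purrr::map_dfr(out, "truth")
  )
}

#' Pipeline recovery harness over replicate synthetic cohorts
#'
#' Generates `n_replicates` cohorts (seeds `config$seed + 1:n_replicates`),
#' runs the full analysis pipeline on each, and reports the quantities the
#' study design cares about: AUROC of the adjusted versus raw plasma HER2
#' copy number for clinical benefit, the Cox PFS hazard ratio of the
#' favorable stratum, the hazard ratio of decreased versus increased week-3
#' ctDNA fraction, and the median week-3 change ratios by response group.
#'
#' @param config An [cohort_config()] object.
#' @param n_replicates Number of replicate cohorts.
#' @return Tibble with one row per replicate: `replicate`, `auroc_apcn`,
#'   `auroc_pcn`, `hr_favorable`, `hr_decreased`, `median_ratio_CR`,
#'   `median_ratio_PR`, `median_ratio_SD_shrinkage`,
#'   `median_ratio_SD_no_shrinkage`, `median_ratio_PD`.
#' @export
recovery_harness <- function(config, n_replicates = 20) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    coh <- simulate_cohort(cfg)
    res <- analyze_cohort(coh$variants, coh$clinical, cn_threshold = config$cn_threshold)
    med <- setNames(res$change_summary$median_ratio, as.character(res$change_summary$response_group))
    g <- function(k) if (k %in% names(med)) unname(med[k]) else NA_real_
    tibble(
      replicate = r,
      auroc_apcn = res$roc_apcn$auroc,
      auroc_pcn = res$roc_pcn$auroc,
      hr_favorable = res$hr_favorable$hr,
      hr_decreased = res$hr_decreased$hr,
      median_ratio_CR = g("CR"),
      median_ratio_PR = g("PR"),
      median_ratio_SD_shrinkage = g("SD_shrinkage"),
      median_ratio_SD_no_shrinkage = g("SD_no_shrinkage"),
      median_ratio_PD = g("PD")
    )
  })
}
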