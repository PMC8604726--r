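---
title: "Methods: tumor-fraction-adjusted copy number and ctDNA-guided trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-fraction-adjusted copy number and ctDNA-guided trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liquidtrial)
library(dplyr)
```

## The problem

In HER2-amplified metastatic colorectal cancer, dual HER2 blockade helps a
minority of patients, and the question is whether plasma circulating tumor
DNA (ctDNA) genotyping can identify them as well as — or better than —
tissue testing. Plasma copy number is a poor surrogate for tumor copy
number because cell-free DNA is a mixture: a strongly amplified tumor that
sheds little DNA looks unamplified in plasma. `liquidtrial` implements the
analysis chain for a single-arm, biomarker-driven trial of this kind:
sample-level ctDNA metrics, baseline biomarker stratification, on-treatment
monitoring, acquired-resistance comparison, and the exact phase-II trial
statistics, together with a synthetic cohort generator that gives every
stage a testable ground truth.

## Sample-level model

Three quantities are derived per plasma sample, all under a diploid,
heterozygous-clonal assumption:

* **Tumor fraction.** A clonal heterozygous somatic variant in a diploid
  genome appears at allele fraction T/2 when a fraction T of the cell-free
  DNA is tumor-derived. The maximum somatic VAF across SNVs, indels and
  fusions therefore estimates `T = 2 * maxVAF / 100`. VAF is kept in
  percent (0–100) everywhere and T as a proportion in [0, 1], fixing the
  units once. VAFs above 50% (possible under LOH or aneuploidy, where the
  assumption fails) cap T at 1 and are flagged. A sample with *no*
  sequence-level somatic call has an undefined — not zero — tumor fraction:
  non-detection is a distinct biological state, and the functions error or
  flag rather than silently return 0.

* **Adjusted plasma copy number (ApCN).** Observed plasma copy number mixes
  tumor signal with the 2-copy normal background:
  `pCN = T * CN_tumor + 2 * (1 - T)`. Inverting,
  `ApCN = (pCN - 2 * (1 - T)) / T`, implemented as `(pCN - 2)/T + 2`, which
  is algebraically identical but floating-point-exact at the two anchor
  points (`pCN = 2` maps to 2 at any T; T = 1 is the identity). Noise at
  low T can drive the raw value negative; the raw value is retained and the
  classification value is clipped at 0 with a flag. T = 0 is an error:
  no adjustment can recover tumor copy number from a sample with no tumor
  signal.

* **Relative clonality.** Each sequence-level call's VAF divided by the
  sample's maximum somatic VAF; strictly below 0.3 is subclonal, 0.3
  exactly is clonal (the boundary follows the strict "less than"
  convention). Amplifications carry no VAF, get no clonality label, and are
  treated as clonal events downstream.

## Baseline stratification

Two baseline factors define the "favorable" stratum: a HER2 copy-number
value at or above a modality-specific threshold, and the absence of
concurrent RTK/RAS/PI3K pathway alterations. The co-alteration screen
counts pathway amplifications plus clonal mutations in ctDNA (subclonal
hits are ignored as minor-clone passengers), and any pathway alteration in
tissue, which reports no clonality. ERBB2 amplification itself is never a
co-alteration — it is the selection biomarker — while ERBB2 point mutations
count. The pathway set defaults to a literature-standard list (EGFR, ERBB2,
ERBB3, MET, FGFR1/2, KRAS/NRAS/HRAS, BRAF, MAP2K1, PIK3CA, PTEN, AKT1) and
is an argument everywhere, since panels differ.

ROC analysis is rank-based: AUROC is `P(score_pos > score_neg) + ½ P(tie)`,
identical to the Mann–Whitney U statistic over n1·n2, and its p-value uses
the tie-corrected normal approximation of U — the natural null test when no
specific test is named for an AUROC. Thresholds are selected by Youden's
J = sensitivity + specificity − 1, with ties broken toward the larger
(more specific) threshold; Youden is an assumption, as ROC-derived cutoffs
rarely state their criterion. Proportions are compared by two-sided
Fisher's exact test by default; an exact McNemar (discordant-pair binomial)
variant is exposed for paired designs, since the same patients are often
genotyped by both modalities.

## Response, monitoring, resistance

Best confirmed response follows RECIST-style confirmation at desk scale: a
CR/PR counts only if a scan at least 28 days later shows the same or a
better category. An unconfirmed response falls back to the best
non-response category actually observed; when the series contains *only*
the unconfirmed response, the fallback is SD — the scan demonstrably showed
non-progression, and demoting it to PD would invent an event. Clinical
benefit is confirmed CR/PR, or SD with PFS of at least 4.0 months
(inclusive; months are days / 30.4375 everywhere).

Week-3 monitoring uses the ratio of week-3 to baseline ctDNA fraction. The
ratio is scale-invariant, "decreased" is strictly below 1, and a collected
week-3 sample with no detectable somatic variant is complete clearance —
ratio 0 — rather than missing data; an uncollected sample is excluded. SD
is split by the sign of the best sum-of-diameters change, with exactly 0
counting as no shrinkage.

Resistance comparison treats alterations as present/absent by
(gene, alteration type, variant label) identity: dosage changes are not
emergence, and a "lost" amplification means the call fell below the
reportable range, not that ApCN declined. Emergent alterations are not
clonality-filtered.

## Trial statistics

The exact single-stage design rejects the null response rate p0 when at
least r responses occur in n patients, with r the smallest integer whose
binomial tail `P(X ≥ r | n, p0)` is at most the one-sided α. Because r is
an integer, attained power is a saw-tooth in n: it can dip back below the
target as n grows (for p0 = 0.05, p1 = 0.30, α = 0.025 the dips below 90%
power are at n = 20, 23 and 24). `single_stage_design()` therefore returns
the smallest n from which power stays at or above target for every larger
n — the convention of the standard single-stage design tables, which
guarantees the stated power under modest over-accrual. For the default
parameters this gives n = 25, r = 5 (attained α 0.0072, power 0.910); a
naive first-crossing scan would stop at n = 21, just before a dip.

Confidence intervals for response rates are exact Clopper–Pearson
(beta-quantile formulation; the lower bound is exactly 0 at x = 0 and the
upper exactly 1 at x = n). Percentages are rounded half-up to integers for
report parity. Survival uses the `survival` package: Kaplan–Meier with the
median defined as the earliest time at which the curve reaches 0.5 or below
(the package computes this from the fit steps; `survfit`'s own median
interpolates when the curve hits 0.5 exactly), Brookmeyer–Crowley log-log
CI for the median, Cox partial likelihood with Efron tie handling and Wald
CIs for binary-factor hazard ratios, and the two-sided log-rank test.
Mann–Whitney is exact by enumeration when the combined sample size is at
most 20 with no ties, otherwise normal-approximated with tie and continuity
corrections — a stated, deterministic switch rather than a software
default.

## The synthetic cohort

The generator is the package's ground truth, not a data fixture. Its
forward model is chosen so the analysis is *exactly* correct in the
noiseless limit: observed plasma CN is `T·CN_true + 2(1 − T)` (the
algebraic inverse of the ApCN formula), and the clonal driver SNV is
emitted at VAF `50·T`, so the pipeline recovers T and CN_true to machine
precision when multiplicative noise is switched off. Defaults describe the
study conditions the analysis assumes:

* tumor fraction log-normal, median 10%, wide (sdlog 1) — ctDNA shedding
  varies over orders of magnitude, which is precisely what confounds raw
  plasma CN;
* true tumor HER2 CN `2 + LogNormal(log 25, 0.8)`, putting meaningful mass
  on both sides of the 16.7-copy benefit threshold;
* reportable ranges VAF ≥ 0.04% and amplification ≥ 2.12 copies, matching
  the plasma assay's stated limits — calls below them are dropped, so
  low-shedders can genuinely lose their amplification call;
* a benefit model (P(benefit) 0.75 above the CN threshold, 0.15 below,
  ×0.2 with a co-alteration; co-alteration prevalence 0.45) that plants the
  association the stratification should recover;
* week-3 clearance multipliers 0 / 0.32 / 0.68 / 1.46 / 1.21 for CR / PR /
  SD-with-shrinkage / SD-without-shrinkage / PD — the observed medians of
  the monitoring analysis this package implements — with log-normal spread;
* exponential PFS/OS with medians 5.6 / 1.6 (PFS) and 16.5 / 5.7 (OS)
  months by benefit stratum, administrative censoring at 24 / 36 months;
* actionable-alteration emergence probability 0.62 at progression and HER2
  amplification loss probability 0.15.

Each patient draws from a seed substream derived from the config seed, so
cohorts are byte-reproducible and enlarging the cohort never reshuffles
existing patients. Tissue NGS CN is generated on the same scale as true
tumor CN; real tissue assays sit on their own scale (which is why the
trial's tissue threshold differs from the ApCN threshold), and the
per-modality ROC threshold selection absorbs exactly this kind of scale
difference.

What the generator does *not* emulate: read-level sequencing error,
germline leakage, clonal evolution beyond presence/absence at three
timepoints, correlated shedding and tumor burden, and non-exponential
survival. Passing tests therefore show the pipeline's logic and arithmetic
are right under the stated model — not that the biological effect sizes in
any real cohort match the defaults.

```{r}
coh <- simulate_cohort(cohort_config(seed = 20180, n_patients = 150))
res <- analyze_cohort(coh$variants, coh$clinical, cn_threshold = 16.7)
res
```

The adjusted copy number out-discriminates the raw plasma value because the
generator's benefit depends on `CN_true`, which shedding hides from `pCN`
but not from ApCN:

```{r}
c(apcn = res$roc_apcn$auroc, pcn = res$roc_pcn$auroc)
```

## Numerical and design choices

* Problem sizes: reference simulations use 400–500 patients (large enough
  that planted effects dominate sampling noise at the package's default
  effect sizes), with smaller cohorts in examples.
* Degenerate inputs error loudly rather than guess: empty assessment
  series, zero baseline ctDNA fraction, single-class ROC labels, all-equal
  scores at threshold selection, zero tumor fraction at adjustment.
* Ties: clonality 1.0 is shared by all calls tied at the maximum VAF;
  Youden ties resolve to the larger threshold; Cox uses Efron.
* The month constant (30.4375 days) is defined once and used everywhere.

## Limitations

The package analyzes call-level assay summaries, not reads; it performs no
variant calling, barcode deduplication or germline subtraction. RECIST is
handled at assessment-category level, not lesion level. The favorable
stratification is deliberately bivariate (copy number + co-alterations);
multivariable modeling of benefit is out of scope.
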