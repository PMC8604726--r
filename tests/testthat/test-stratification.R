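test_that("co-alteration screen counts clonal ctDNA events and excludes the selection biomarker", {
  v <- dplyr::bind_rows(
    plasma_calls(vafs = c(10, 4), genes = c("TP53", "KRAS")), # KRAS clonality 0.4
    plasma_calls(amp_genes = "ERBB2", amp_pcn = 20, patient_id = "P1")
  )
  hit <- detect_concurrent_alterations(v)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$gene, "KRAS")

  # subclonal pathway mutation does not count
  v2 <- plasma_calls(vafs = c(10, 1), genes = c("TP53", "PIK3CA")) # clonality 0.1
  expect_equal(nrow(detect_concurrent_alterations(v2)), 0)

  # ERBB2 amplification alone never counts; an ERBB2 point mutation does
  v3 <- plasma_calls(amp_genes = "ERBB2", amp_pcn = 30)
  expect_equal(nrow(detect_concurrent_alterations(v3)), 0)
  v4 <- plasma_calls(vafs = 10, genes = "ERBB2")
  expect_equal(detect_concurrent_alterations(v4)$gene, "ERBB2")

  # pathway amplification counts regardless of clonality machinery
  v5 <- plasma_calls(vafs = 10, genes = "TP53", amp_genes = "MET", amp_pcn = 5)
  expect_equal(detect_concurrent_alterations(v5)$gene, "MET")
})

test_that("tissue co-alterations are not clonality-filtered", {
  v <- tibble::tibble(
    patient_id = "P1", sample_type = "tissue", timepoint = "baseline",
    gene = c("KRAS", "ERBB2"), alteration_type = c("SNV", "amplification"),
    variant_label = c("KRAS:m1", "ERBB2:amp"),
    vaf_percent = NA_real_, plasma_cn = NA_real_, tissue_cn = c(NA, 70)
  )
  hit <- detect_concurrent_alterations(v)
  expect_equal(hit$gene, "KRAS")
})

test_that("favorable classification requires threshold CN and a clean pathway", {
  st <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    modality = "ctdna",
    her2_cn_value = c(16.7, 100, 16.6),
    n_concurrent = c(0L, 1L, 0L),
    has_concurrent = c(FALSE, TRUE, FALSE)
  )
  out <- classify_favorable(st, 16.7)
  expect_equal(out$favorable, c(TRUE, FALSE, FALSE)) # inclusive threshold; co-alteration vetoes
  st$her2_cn_value[1] <- NA
  expect_error(classify_favorable(st, 16.7), "missing")
})

test_that("favorable status is monotone in the copy-number value", {
  set.seed(5)
  for (i in 1:50) {
    cn <- runif(1, 0, 120)
    co <- runif(1) < 0.5
    st <- tibble::tibble(
      patient_id = "X", modality = "ctdna", her2_cn_value = cn,
      n_concurrent = as.integer(co), has_concurrent = co
    )
    f1 <- classify_favorable(st, 30)$favorable
    st$her2_cn_value <- cn + runif(1, 0, 50)
    f2 <- classify_favorable(st, 30)$favorable
    expect_false(f1 && !f2) # raising CN never flips favorable -> unfavorable
  }
})

test_that("AUROC matches brute-force pairwise concordance", {
  brute <- function(s, l) {
    pos <- s[as.logical(l)]
    neg <- s[!as.logical(l)]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(auroc(1:4, c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    s <- sample(1:10, n, replace = TRUE) # ties on purpose
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(s, l), brute(s, l))
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUROC is antisymmetric under score negation", {
  set.seed(32)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- rnorm(n)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auroc(s, l), 1 - auroc(-s, l))
  }
})

test_that("AUROC equals Mann-Whitney U / (n1 n2) on random instances", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(3:15, 1)
    n2 <- sample(3:15, 1)
    pos <- rnorm(n1, mean = runif(1, 0, 2))
    neg <- rnorm(n2)
    u <- suppressWarnings(stats::wilcox.test(pos, neg)$statistic)
    expect_equal(auroc(c(pos, neg), rep(c(TRUE, FALSE), c(n1, n2))),
      unname(u) / (n1 * n2))
  }
})

test_that("AUROC p-value behaves at the null and under separation", {
  set.seed(34)
  # identical distributions, large n: no signal
  s <- rnorm(400)
  l <- rep(0:1, 200)
  expect_gt(auroc_pvalue(s, l), 0.01)
  # perfect separation at n = 10 + 10 is highly significant
  expect_lt(auroc_pvalue(c(1:10, 101:110), rep(c(0, 1), each = 10)), 0.001)
  # all scores tied: p = 1
  expect_equal(auroc_pvalue(rep(3, 10), rep(0:1, 5)), 1)
  expect_error(auroc_pvalue(1:4, rep(TRUE, 4)), "both classes")
})

test_that("Youden threshold selection matches an exhaustive scan and breaks ties upward", {
  brute_youden <- function(s, l) {
    l <- as.logical(l)
    thr <- sort(unique(s))
    j <- vapply(thr, function(t) mean(s[l] >= t) + mean(s[!l] < t) - 1, 0)
    max(thr[j == max(j)])
  }
  set.seed(35)
  for (i in 1:30) {
    n <- sample(6:25, 1)
    s <- sample(1:8, n, replace = TRUE)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    if (length(unique(s)) < 2) next
    expect_equal(select_threshold(roc_curve(s, l)), brute_youden(s, l))
  }
  # perfect separation: smallest positive-class score is selected
  r <- roc_curve(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(select_threshold(r), 10)
  expect_equal(r$auroc, 1)
  # degenerate scores cannot give a threshold
  expect_error(select_threshold(roc_curve(rep(1, 4), c(0, 0, 1, 1))), "all scores")
})

test_that("roc_curve operating points are sorted and bounded", {
  set.seed(36)
  s <- rnorm(40)
  l <- rep(0:1, 20)
  r <- roc_curve(s, l)
  p <- tidy(r)
  expect_true(!is.unsorted(p$threshold))
  expect_true(all(p$sensitivity >= 0 & p$sensitivity <= 1))
  expect_true(all(p$specificity >= 0 & p$specificity <= 1))
  expect_true(r$auroc >= 0 && r$auroc <= 1)
  g <- glance(r)
  expect_equal(g$auroc, r$auroc)
})

test_that("proportion comparison reproduces exact hypergeometric enumeration", {
  # enumeration oracle: two-sided Fisher by point-probability summation
  fisher_enum <- function(x1, n1, x2, n2) {
    m <- x1 + x2
    ks <- max(0, m - n2):min(n1, m)
    probs <- stats::dhyper(ks, n1, n2, m)
    sum(probs[probs <= stats::dhyper(x1, n1, n2, m) * (1 + 1e-7)])
  }
  expect_equal(compare_proportions(0, 10, 0, 10)$p_value, 1)
  expect_equal(
    compare_proportions(5, 5, 0, 5)$p_value,
    fisher_enum(5, 5, 0, 5)
  )
  set.seed(37)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    expect_equal(
      compare_proportions(x1, n1, x2, n2)$p_value,
      fisher_enum(x1, n1, x2, n2),
      tolerance = 1e-7
    )
  }
  # the trial's 4/21 vs 14/21 contrast is clearly significant
  expect_lt(compare_proportions(4, 21, 14, 21)$p_value, 0.01)
  expect_error(compare_proportions(6, 5, 0, 5), "x1")
})

test_that("paired proportion comparison is the exact binomial test on discordant pairs", {
  expect_equal(compare_paired_proportions(0, 0)$p_value, 1)
  expect_equal(
    compare_paired_proportions(2, 10)$p_value,
    stats::binom.test(2, 12, 0.5)$p.value
  )
})

test_that("biomarker status assembles per-patient CN and co-alteration flags per modality", {
  v <- dplyr::bind_rows(
    plasma_calls(vafs = c(10, 8), genes = c("TP53", "KRAS"),
      amp_genes = "ERBB2", amp_pcn = 6, patient_id = "A"),
    plasma_calls(vafs = 20, genes = "TP53",
      amp_genes = "ERBB2", amp_pcn = 10, patient_id = "B")
  )
  st <- biomarker_status(v, "ctdna")
  expect_equal(nrow(st), 2)
  a <- st[st$patient_id == "A", ]
  expect_true(a$has_concurrent)
  expect_equal(a$her2_cn_value, (6 - 2) / 0.2 + 2) # ApCN at T = 0.2
  b <- st[st$patient_id == "B", ]
  expect_false(b$has_concurrent)
  expect_equal(b$her2_cn_value, (10 - 2) / 0.4 + 2)
})
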