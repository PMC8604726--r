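assess <- function(days, cats, sld = NA_real_) {
  data.frame(day = days, category = cats, sld = rep_len(sld, length(days)))
}

test_that("response confirmation requires a repeat scan at least 28 days later", {
  expect_equal(confirm_best_response(assess(c(42, 84), c("PR", "PR"))), "PR")
  # 28-day gap exactly meets the boundary
  expect_equal(confirm_best_response(assess(c(42, 70), c("CR", "CR"))), "CR")
  # 27-day gap does not
  expect_equal(confirm_best_response(assess(c(42, 69), c("PR", "PR"))), "SD")
  # a later better category confirms the earlier response
  expect_equal(confirm_best_response(assess(c(42, 84), c("PR", "CR"))), "PR")
  # unconfirmed PR followed by PD demotes to the best non-response observed
  expect_equal(confirm_best_response(assess(c(42, 84), c("PR", "PD"))), "PD")
  expect_equal(confirm_best_response(assess(c(42, 84, 126), c("SD", "PR", "PD"))), "SD")
  expect_equal(confirm_best_response(assess(42, "SD")), "SD")
  expect_equal(confirm_best_response(assess(42, "NE")), "NE")
  expect_error(confirm_best_response(assess(numeric(), character())), "empty")
  expect_error(confirm_best_response(assess(42, "XX")), "category")
})

test_that("clinical benefit is response, or stable disease for four or more months", {
  expect_equal(
    classify_benefit(c("PR", "SD", "SD", "PD"), c(2.0, 4.0, 3.9, 10)),
    c(TRUE, TRUE, FALSE, FALSE)
  )
  expect_true(classify_benefit("CR", NA)) # PFS not needed for responders
  expect_error(classify_benefit("SD", NA), "PFS")
})

test_that("proportional ctDNA change handles clearance and the ratio boundary", {
  expect_equal(ctdna_change(0.2, 0.064)$ratio, 0.32)
  expect_equal(ctdna_change(0.2, 0.064)$direction, "decreased")
  # complete clearance: week-3 undetectable is ratio 0
  cc <- ctdna_change(0.1, NA)
  expect_equal(cc$ratio, 0)
  expect_equal(cc$direction, "decreased")
  # ratio exactly 1 is "increased" (decreased is strict)
  expect_equal(ctdna_change(0.1, 0.1)$direction, "increased")
  expect_error(ctdna_change(0, 0.1), class = "liquidtrial_undefined_change")
  expect_error(ctdna_change(NA, 0.1), class = "liquidtrial_undefined_change")
})

test_that("proportional change is scale-invariant and its dichotomy exhaustive", {
  set.seed(41)
  b <- runif(50, 0.001, 1)
  w <- runif(50, 0, 1)
  base <- ctdna_change(b, w)
  scaled <- ctdna_change(3.7 * b, 3.7 * w)
  expect_equal(base$ratio, scaled$ratio)
  expect_true(all(base$direction %in% c("decreased", "increased")))
  expect_equal(base$direction == "decreased", base$ratio < 1)
})

test_that("cohort change table uses collected week-3 samples and clearance convention", {
  v <- dplyr::bind_rows(
    plasma_calls(vafs = 10, patient_id = "A"),
    plasma_calls(vafs = 3.2, patient_id = "A", timepoint = "week3"),
    plasma_calls(vafs = 5, patient_id = "B") # week3 collected but cleared
  )
  cl <- tibble::tibble(
    patient_id = c("A", "B"), assessment_day = 42, assessment_category = "PR",
    sld_change_percent = -40, pfs_months = 6, pfs_event = TRUE,
    os_months = 12, os_event = FALSE, week3_collected = TRUE
  )
  tab <- ctdna_change_table(v, cl)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ratio[tab$patient_id == "A"], 0.32)
  expect_equal(tab$ratio[tab$patient_id == "B"], 0) # collected, nothing detected
  # without collection info, only patients with week-3 rows are usable
  tab2 <- ctdna_change_table(v)
  expect_equal(tab2$patient_id, "A")
})

test_that("change-by-response medians split SD by tumor shrinkage", {
  changes <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    baseline_fraction = 0.1, week3_fraction = c(0, 0.02, 0.09, 0.15),
    ratio = c(0, 0.2, 0.9, 1.5),
    direction = c("decreased", "decreased", "decreased", "increased")
  )
  records <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    best_confirmed = c("CR", "PR", "SD", "SD"),
    best_sld_change = c(-100, -50, -10, 0) # 0 counts as no shrinkage
  )
  out <- summarize_change_by_response(changes, records)
  expect_equal(as.character(out$response_group),
    c("CR", "PR", "SD_shrinkage", "SD_no_shrinkage"))
  expect_equal(out$median_ratio, c(0, 0.2, 0.9, 1.5))
  # empty categories (PD here) are absent rows
  expect_false("PD" %in% as.character(out$response_group))
})

test_that("synthetic cohorts order change medians with response and favor decreased ctDNA", {
  coh <- small_cohort(seed = 314, n = 400)
  rec <- clinical_records(coh$clinical)
  chg <- ctdna_change_table(coh$variants, coh$clinical)
  med <- summarize_change_by_response(chg, rec)
  m <- setNames(med$median_ratio, as.character(med$response_group))
  expect_true(m["CR"] <= m["PR"])
  expect_true(m["PR"] <= m["SD_shrinkage"])
  expect_true(m["SD_shrinkage"] < m["SD_no_shrinkage"])
  # responders' ctDNA drops, growers' rises
  expect_lt(m["PR"], 1)
  expect_gt(m["SD_no_shrinkage"], 1)
  # decreased ctDNA fraction predicts longer PFS (protective hazard ratio)
  d <- dplyr::inner_join(chg, rec, by = "patient_id")
  hr <- cox_hr_binary(d$pfs_months, d$pfs_event, d$direction == "decreased")
  expect_lt(hr$hr, 1)
})
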