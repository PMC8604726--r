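test_that("critical value matches brute-force binomial tail summation", {
  tail_ge <- function(r, n, p) sum(stats::dbinom(r:n, n, p))
  brute_r <- function(n, p0, alpha) {
    for (r in 1:n) if (tail_ge(r, n, p0) <= alpha) return(r)
    NA_integer_
  }
  expect_equal(design_critical_value(25, 0.05, 0.025), 5)
  expect_equal(design_critical_value(1, 0.5, 0.6), 1)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    p0 <- runif(1, 0.02, 0.5)
    r <- design_critical_value(n, p0, 0.025)
    expect_equal(r, brute_r(n, p0, 0.025))
    # defining inequalities: P(X >= r) <= alpha < P(X >= r - 1)
    expect_lte(tail_ge(r, n, p0), 0.025)
    expect_gt(tail_ge(r - 1, n, p0), 0.025)
  }
  expect_error(design_critical_value(3, 0.9, 0.001), "no critical value")
})

test_that("single-stage design search is minimal and reports attained error rates", {
  d <- single_stage_design(p0 = 0.05, p1 = 0.30, alpha = 0.025, power = 0.90)
  expect_equal(d$n, 25)
  expect_equal(d$r, 5)
  expect_gte(d$power, 0.90)
  expect_lte(d$attained_alpha, 0.025)
  # oracle: brute-force (n, r) table, then the smallest n from which the
  # saw-toothed power never dips below target again
  brute_design <- function(p0, p1, alpha, power, horizon = 200) {
    tab <- t(sapply(1:horizon, function(n) {
      for (r in 1:n) {
        if (sum(stats::dbinom(r:n, n, p0)) <= alpha) {
          return(c(r, sum(stats::dbinom(r:n, n, p1))))
        }
      }
      c(NA, 0)
    }))
    ok <- tab[, 2] >= power
    n <- if (all(ok)) 1 else max(which(!ok)) + 1
    c(n, tab[n, 1])
  }
  expect_equal(c(d$n, d$r), brute_design(0.05, 0.30, 0.025, 0.90))
  d80 <- single_stage_design(0.05, 0.30, 0.025, 0.80)
  expect_equal(c(d80$n, d80$r), brute_design(0.05, 0.30, 0.025, 0.80))
  # attained power at the returned n never dips below target at any larger n
  dips <- sapply(d$n:200, function(n) {
    r <- design_critical_value(n, 0.05, 0.025)
    sum(stats::dbinom(r:n, n, 0.30))
  })
  expect_true(all(dips >= 0.90))
  # certain success under the alternative: first design with a valid critical value
  dc <- single_stage_design(0.05, 1.0, 0.025, 0.90)
  expect_equal(dc$power, 1)
  expect_lte(dc$attained_alpha, 0.025)
  expect_equal(dc$n, 2) # 0.05^2 = 0.0025 <= 0.025 at r = n = 2
  expect_error(single_stage_design(0.05, 0.052, 0.025, 0.999, n_max = 50), "no design")
  expect_equal(tidy(d)$n, 25)
})

test_that("Clopper-Pearson intervals match the inverted-test oracle and printed trial values", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    oracle <- stats::binom.test(x, n)$conf.int
    expect_equal(c(ci$lower, ci$upper), as.numeric(oracle), tolerance = 1e-10)
  }
  # boundary exactness
  expect_identical(clopper_pearson(0, 13)$lower, 0)
  expect_identical(clopper_pearson(13, 13)$upper, 1)
  # the trial's printed intervals, after integer-percent rounding
  expect_equal(floor(100 * clopper_pearson(8, 27)[c("lower", "upper")] + 0.5),
               tibble::tibble(lower = 14, upper = 50), ignore_attr = TRUE)
  expect_equal(floor(100 * clopper_pearson(7, 25)[c("lower", "upper")] + 0.5),
               tibble::tibble(lower = 12, upper = 49), ignore_attr = TRUE)
  expect_equal(floor(100 * clopper_pearson(0, 13)[c("lower", "upper")] + 0.5),
               tibble::tibble(lower = 0, upper = 25), ignore_attr = TRUE)
  expect_error(clopper_pearson(5, 4), "x <= n")
})

test_that("Clopper-Pearson coverage is conservative", {
  set.seed(53)
  n <- 30
  p <- 0.2
  x <- rbinom(2000, n, p)
  ci <- clopper_pearson(x, n)
  expect_gte(mean(ci$lower <= p & p <= ci$upper), 0.95)
})

test_that("ORR reproduces the trial's response-rate arithmetic", {
  mk <- function(x, n) {
    tibble::tibble(best_confirmed = rep(c("PR", "PD"), c(x, n - x)))
  }
  o1 <- orr(mk(8, 27))
  expect_equal(o1$orr_pct, 30)
  expect_equal(c(o1$lower_pct, o1$upper_pct), c(14, 50))
  o2 <- orr(mk(7, 25))
  expect_equal(o2$orr_pct, 28)
  expect_equal(c(o2$lower_pct, o2$upper_pct), c(12, 49))
  o3 <- orr(mk(0, 13))
  expect_equal(o3$orr_pct, 0)
  expect_equal(c(o3$lower_pct, o3$upper_pct), c(0, 25))
})

test_that("KM estimate equals the empirical survival function without censoring", {
  f <- km_fit(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(tidy(f)$estimate, c(0.75, 0.5, 0.25, 0))
  expect_equal(f$median, 2)
  set.seed(54)
  t <- rexp(40)
  f2 <- km_fit(t, rep(TRUE, 40))
  emp <- vapply(sort(t), function(u) mean(t > u), 0)
  expect_equal(tidy(f2)$estimate, emp)
})

test_that("KM handles censoring per the hand-computed product-limit table", {
  # times 1,2+,3,4,5+,6 : steps at 1 (6 at risk), 3 (4 at risk), 4, 6
  f <- km_fit(c(1, 2, 3, 4, 5, 6), c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  td <- tidy(f)
  expect_equal(td$estimate[td$time == 1], 5 / 6)
  expect_equal(td$estimate[td$time == 3], 5 / 6 * 3 / 4)
  expect_equal(td$estimate[td$time == 4], 5 / 6 * 3 / 4 * 2 / 3)
  expect_equal(td$estimate[td$time == 6], 0)
  expect_equal(f$median, 4) # first time with S(t) <= 0.5
  # all censored: median not reached
  expect_true(is.na(km_fit(c(5, 6, 7), c(FALSE, FALSE, FALSE))$median))
  expect_error(km_fit(numeric(), logical()), "no observations")
})

test_that("Cox hazard ratio for a binary factor behaves at exchangeability and by closed form", {
  set.seed(55)
  t <- rexp(60)
  e <- rep(TRUE, 60)
  g <- rep(c(TRUE, FALSE), 30)
  hr <- cox_hr_binary(t, e, g)
  expect_gt(hr$hr, 0.6)
  expect_lt(hr$hr, 1.6)
  expect_true(hr$conf_low < 1 && hr$conf_high > 1)
  # two subjects, one event each, no ties: partial likelihood
  # L(b) = e^(b g1) / (e^(b g1) + e^(b g2)) maximised at the boundary,
  # flagged as a monotone likelihood
  w <- capture_warnings(cox_hr_binary(c(1, 2), c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_true(any(grepl("no events", w)))
  expect_error(cox_hr_binary(t, e, rep(TRUE, 60)), "both group levels")
})

test_that("Cox estimate recovers a simulated true hazard ratio", {
  set.seed(56)
  reps <- 30
  est <- replicate(reps, {
    n <- 200
    g <- rep(c(TRUE, FALSE), each = n)
    t <- c(rexp(n, 0.3), rexp(n, 1)) # true HR = 0.3
    cox_hr_binary(t, rep(TRUE, 2 * n), g)$hr
  })
  expect_gte(mean(est > 0.2 & est < 0.45), 0.95)
})

test_that("log-rank test separates groups and is calibrated at the null", {
  set.seed(57)
  t <- c(rexp(50, 0.2), rexp(50, 1.5))
  g <- rep(c(TRUE, FALSE), each = 50)
  expect_lt(logrank_test(t, rep(TRUE, 100), g)$p_value, 0.01)
  # permuted labels: no signal
  p_null <- replicate(200, {
    gg <- sample(g)
    logrank_test(t, rep(TRUE, 100), gg)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_error(logrank_test(t, rep(TRUE, 100), rep(TRUE, 100)), "two groups")
})

test_that("Mann-Whitney p-values match full enumeration for small samples", {
  # enumeration oracle over all choose(nx + ny, nx) label assignments
  enum_p <- function(x, y) {
    pooled <- c(x, y)
    nx <- length(x)
    u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    combs <- utils::combn(length(pooled), nx)
    us <- apply(combs, 2, function(idx) {
      xx <- pooled[idx]
      yy <- pooled[-idx]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    })
    n1n2 <- nx * length(y)
    mean(abs(us - n1n2 / 2) >= abs(u_obs - n1n2 / 2) - 1e-9)
  }
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$u, 0)
  expect_equal(out$p_value, 1 / 3)
  expect_equal(out$method, "exact")
  set.seed(58)
  for (i in 1:15) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    vals <- sample(1:1000, nx + ny) # distinct -> exact path
    x <- vals[1:nx]
    y <- vals[-(1:nx)]
    expect_equal(mann_whitney(x, y)$p_value, enum_p(x, y))
  }
  expect_error(mann_whitney(numeric(), 1:3), "non-empty")
})

test_that("Mann-Whitney falls back to the corrected normal approximation", {
  x <- c(1, 1, 2, 5)
  y <- c(2, 3, 3, 8) # ties force the approximation
  out <- mann_whitney(x, y)
  expect_equal(out$method, "normal_approx")
  oracle <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(out$p_value, oracle$p.value)
  # identical samples: no evidence of a shift (continuity correction keeps
  # the approximate p below 1)
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
})
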