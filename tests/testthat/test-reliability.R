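make_tally_manifest <- function(n_subjects = 42, fail_cond4 = 5) {
  m <- expand.grid(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                   device = c("waist", "head"), condition = 1:6,
                   attempt = 1:2, stringsAsFactors = FALSE)
  m$file <- "x.csv"; m$failed <- FALSE; m$failure_reason <- NA_character_
  # first `fail_cond4` subjects fail attempt 1 of condition 4 (both devices)
  bad <- m$subject_id %in% sprintf("S%02d", seq_len(fail_cond4)) &
    m$condition == 4 & m$attempt == 1
  m$failed[bad] <- TRUE
  m$failure_reason[bad] <- "feet_moved"
  m
}

npl_from_manifest <- function(m) {
  data.frame(subject_id = m$subject_id, device = m$device,
             condition = m$condition, attempt = m$attempt,
             npl_ap = seq_len(nrow(m)), npl_total = seq_len(nrow(m)) + 1,
             duration_s = 49.98, stringsAsFactors = FALSE)
}

test_that("failure exclusion retains the right trials and tallies passes", {
  m <- make_tally_manifest(42, fail_cond4 = 5)
  npl <- npl_from_manifest(m)
  ex <- exclude_failures(npl, m)
  expect_equal(nrow(ex$retained), nrow(m) - sum(m$failed))
  pc <- ex$tally$per_condition
  expect_equal(pc$n_passed_both[pc$condition == 4], 37)
  expect_equal(pc$n_total, rep(42, 6))
  expect_equal(pc$n_passed_both[pc$condition != 4], rep(42, 5))
  expect_equal(ex$tally$n_passed_all_conditions, 37)
  expect_equal(ex$tally$n_failed_trials, sum(m$failed))

  # zero failures: everything retained, tallies equal totals
  m0 <- make_tally_manifest(10, fail_cond4 = 0)
  ex0 <- exclude_failures(npl_from_manifest(m0), m0)
  expect_equal(nrow(ex0$retained), nrow(m0))
  expect_equal(ex0$tally$n_passed_all_conditions, 10)

  # all failed: empty retained set plus a warning, no crash
  mall <- make_tally_manifest(4, 0); mall$failed <- TRUE
  expect_warning(exall <- exclude_failures(npl_from_manifest(mall), mall),
                 "nothing retained")
  expect_equal(nrow(exall$retained), 0)

  # result without a manifest entry is a validation error
  orphan <- npl_from_manifest(m)[1, ]; orphan$subject_id <- "ZZ"
  expect_error(exclude_failures(orphan, m), "without a manifest entry")
})

test_that("spearman_rho matches monotone contracts and the midrank oracle", {
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # tied case against the brute-force midrank computation
  xt <- c(1, 2, 2, 4); yt <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(xt, yt), oracle_spearman(xt, yt))
  set.seed(20)
  for (rep in 1:10) {
    a <- sample(1:8, 30, replace = TRUE)  # heavy ties
    b <- a + sample(1:4, 30, replace = TRUE)
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b))
  }
  const <- spearman_rho(rep(1, 5), 1:5)
  expect_true(is.na(const))
  expect_equal(attr(const, "reason"), "constant input")
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("ICC(2,1) agrees with an aov-based ANOVA oracle on random matrices", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(4:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = 2), n, k) + rnorm(n, sd = 2)
    est <- icc_2_1(m)
    expect_equal(est$icc, oracle_icc21(m), tolerance = 1e-10)
    expect_lte(est$ci_low, est$icc)
    expect_gte(est$ci_high, est$icc)
  }
})

test_that("ICC(2,1) point and CI reproduce independently computed references", {
  # reference values from an independent variance-components implementation
  m1 <- matrix(c(10.1091, 11.0017, 8.2471, 6.3978, 8.6067, 6.9958,
                 10.8757, 14.7159, 7.1792, 6.7944, 11.0119, 10.613),
               ncol = 2, byrow = TRUE)
  e1 <- icc_2_1(m1)
  expect_equal(e1$icc, 0.708069006352, tolerance = 1e-9)
  # the reference implementation reports its CI rounded to 2 decimals
  expect_equal(round(e1$ci_low, 2), -0.21)
  expect_equal(round(e1$ci_high, 2), 0.95)

  m2 <- matrix(c(23.6374, 29.7543, 24.2323, 48.1059, 37.7824, 53.1695,
                 59.7205, 56.2836, 32.9853, 35.3302, 40.2321, 41.8502,
                 39.8549, 50.3788, 45.3711, 42.6278, 61.3251, 42.6408,
                 45.826, 54.9951, 40.3152, 60.8855, 63.1071, 62.6403),
               ncol = 3, byrow = TRUE)
  e2 <- icc_2_1(m2)
  expect_equal(e2$icc, 0.580093013794, tolerance = 1e-9)
  expect_equal(round(e2$ci_low, 2), 0.17)
  expect_equal(round(e2$ci_high, 2), 0.88)
})

test_that("ICC(2,1) degenerate and invariance behavior", {
  # identical columns with real row variance: perfect agreement
  base <- c(1, 5, 9, 13)
  expect_equal(icc_2_1(cbind(base, base))$icc, 1)
  # zero total variance: undefined, returned as absent
  flat <- icc_2_1(matrix(3, 4, 2))
  expect_true(is.na(flat$icc))
  expect_equal(flat$reason, "zero total variance")
  expect_error(icc_2_1(matrix(c(1, NA, 3, 4), 2, 2)), "missing cells")
  # invariant under x -> a x + b
  set.seed(22)
  m <- matrix(rnorm(20), 10, 2) + rnorm(10)
  expect_equal(icc_2_1(3.7 * m - 11)$icc, icc_2_1(m)$icc)
  expect_equal(icc_2_1(3.7 * m - 11)$ci_low, icc_2_1(m)$ci_low)
})

test_that("ICC recovers the designed variance-component ratio at n = 500", {
  set.seed(23)
  n <- 500
  row_effect <- rnorm(n, sd = sqrt(3))
  m <- row_effect + matrix(rnorm(2 * n, sd = 1), n, 2)
  expect_equal(icc_2_1(m)$icc, 0.75, tolerance = 0.05)
})

test_that("ICC confidence interval covers the generating value ~95% of the time", {
  set.seed(24)
  reps <- 500L; hits <- 0L
  for (r in seq_len(reps)) {
    m <- rnorm(42, sd = sqrt(3)) + matrix(rnorm(84), 42, 2)
    est <- icc_2_1(m)
    hits <- hits + (est$ci_low <= 0.75 && 0.75 <= est$ci_high)
  }
  expect_gt(hits / reps, 0.92)
  expect_lt(hits / reps, 0.98)
})

test_that("Fisher-z comparison matches its closed form and is antisymmetric", {
  same <- compare_correlations_fisher(0.6, 50, 0.6, 80)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_correlations_fisher(0.9, 100, 0.5, 100)
  z_ref <- (atanh(0.9) - atanh(0.5)) / sqrt(1 / 97 + 1 / 97)
  expect_equal(cmp$z_statistic, z_ref)
  expect_equal(cmp$p_value, 2 * pnorm(-abs(z_ref)))

  rev <- compare_correlations_fisher(0.5, 100, 0.9, 100)
  expect_equal(rev$z_statistic, -cmp$z_statistic)
  expect_equal(rev$p_value, cmp$p_value)
  expect_error(compare_correlations_fisher(1, 10, 0.5, 10), "< 1")
})

test_that("Kruskal-Wallis reproduces the hand-computable example and edge cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2L)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  expect_equal(kruskal_wallis(list(c(5, 5, 5), c(5, 5)))$H, 0)
  expect_equal(kruskal_wallis(list(c(5, 5, 5), c(5, 5)))$p_value, 1)

  # invariance to within-group shuffling
  set.seed(25)
  g1 <- rnorm(10); g2 <- rnorm(12) + 1
  expect_equal(kruskal_wallis(list(sample(g1), sample(g2)))$H,
               kruskal_wallis(list(g1, g2))$H)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("Anderson-Darling keeps its size on normal data and detects skew", {
  set.seed(26)
  keep <- 0L; reps <- 200L
  for (r in seq_len(reps)) {
    res <- anderson_darling_normal(rnorm(5000))
    keep <- keep + !res$reject
  }
  expect_gte(keep / reps, 0.94)

  expect_true(anderson_darling_normal(rexp(5000))$reject)

  # location-scale invariance of the estimated-parameter statistic
  x <- rnorm(200)
  expect_equal(anderson_darling_normal(3 * x + 7)$A2,
               anderson_darling_normal(x)$A2)
  expect_error(anderson_darling_normal(rep(1, 20)), "constant")
  expect_error(anderson_darling_normal(rnorm(5)), "n >= 8")
})
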