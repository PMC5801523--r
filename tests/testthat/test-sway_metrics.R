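test_that("NPL matches closed forms and the brute-force summation oracle", {
  expect_equal(normalized_path_length(rep(7, 100), 50), 0)
  # monotone ramp 0 -> 100 mG over 50 s telescopes to 2 mG/sec
  expect_equal(normalized_path_length(seq(0, 100, length.out = 2500), 50), 2)
  # 1 Hz sinusoid, amplitude 10 mG, sampled 50 Hz for 50 s
  t <- (0:2499) / 50
  x <- 10 * sin(2 * pi * 1 * t)
  got <- normalized_path_length(x, 50)
  expect_equal(got, oracle_npl(x, 50), tolerance = 1e-12)
  expect_equal(got, 4 * 1 * 10, tolerance = 0.01)  # ~ 4 f A
  expect_error(normalized_path_length(5, 50), "2 samples")
})

test_that("NPL is translation-invariant and scale-equivariant", {
  set.seed(10)
  for (rep in 1:20) {
    x <- rnorm(sample(10:500, 1), sd = runif(1, 0.1, 50))
    c0 <- runif(1, -1000, 1000); k <- runif(1, -5, 5)
    expect_equal(normalized_path_length(x + c0, 50),
                 normalized_path_length(x, 50))
    expect_equal(normalized_path_length(k * x, 50),
                 abs(k) * normalized_path_length(x, 50))
    expect_gte(normalized_path_length(x, 50), 0)
  }
})

test_that("total NPL obeys its closed forms and norm inequalities", {
  # constant per-step difference (3,4,0): Pythagorean path 5 per step
  acc <- apply(matrix(c(3, 4, 0), 2500, 3, byrow = TRUE), 2, cumsum)
  expect_equal(total_npl(acc, 50), 2499 * 5 / 50)
  expect_equal(total_npl(make_acc(100), 50), 0)  # constant series

  # single-axis motion: total equals the axis NPL, all variants agree
  set.seed(11)
  x <- rnorm(200)
  one <- cbind(x = x, y = 0, z = 0)
  expect_equal(total_npl(one, 50), normalized_path_length(x, 50))
  expect_equal(total_npl(one, 50, "axis_norm"), normalized_path_length(x, 50))

  # triangle inequalities, fuzzed
  for (rep in 1:20) {
    acc <- matrix(rnorm(3 * 100), ncol = 3)
    per_axis <- apply(acc, 2, normalized_path_length, duration_s = 50)
    tot <- total_npl(acc, 50)
    expect_gte(tot, max(per_axis) - 1e-12)
    expect_lte(tot, sum(per_axis) + 1e-12)
  }
})

test_that("total-NPL variants differ as designed on gravity-offset data", {
  set.seed(12)
  sway <- lowpass_filter(rnorm(1000, sd = 10), 50)
  acc <- cbind(x = sway, y = 1000, z = 0)
  # path3d ignores the constant offset; the magnitude variant does not
  shifted <- acc; shifted[, "y"] <- 0
  expect_equal(total_npl(acc, 50), total_npl(shifted, 50))
  expect_false(isTRUE(all.equal(total_npl(acc, 50, "magnitude"),
                                total_npl(shifted, 50, "magnitude"))))
})

test_that("trial_npl runs the full chain and agrees with an end-to-end oracle", {
  set.seed(13)
  fs <- 50
  sway <- 8 * sin(2 * pi * 0.4 * (0:2999) / fs) + rnorm(3000)
  acc <- cbind(x = 0.3 * sway, y = 1000 + rnorm(3000), z = sway)
  tr <- make_trial(acc, fs = fs, device = "waist")
  res <- trial_npl(tr)
  expect_s3_class(res, "npl_result")
  expect_equal(res$duration_s, 49.98)
  expect_gte(res$npl_total, res$npl_ap)

  # independent reimplementation: trim by time, DC-matched Butterworth via
  # the difference equation, explicit summation
  ba <- oracle_butter(4, 1.25, fs)
  keep <- ((tr$timestamps_ms - tr$timestamps_ms[1]) / 1000) >= 10
  filt1 <- function(v) v[1] + oracle_filter(ba, v - v[1])
  f <- apply(acc[keep, ], 2, filt1)
  dur <- diff(range(tr$timestamps_ms[keep])) / 1000
  expect_equal(res$npl_ap, oracle_npl(f[, "z"], dur), tolerance = 1e-9)
  steps <- sqrt(rowSums(diff(f)^2))
  expect_equal(res$npl_total, sum(steps) / dur, tolerance = 1e-9)
})

test_that("zero-sway and single-axis trials hit the degenerate contracts", {
  gravity_only <- make_trial(make_acc(3000))
  res <- trial_npl(gravity_only)
  expect_equal(res$npl_ap, 0)
  expect_equal(res$npl_total, 0)

  z <- 5 * sin(2 * pi * 0.3 * (0:2999) / 50)
  ap_only <- make_trial(cbind(x = 0, y = 0, z = z))
  res2 <- trial_npl(ap_only)
  expect_equal(res2$npl_total, res2$npl_ap)

  failed <- make_trial(make_acc(3000), failed = TRUE,
                       failure_reason = "feet_moved")
  expect_error(trial_npl(failed), "failed trial")
})

test_that("standardization and composite follow their definitions", {
  ref <- normative_reference(1:6, location = rep(10, 6), scale = rep(4, 6))
  expect_equal(standardize_npl(10, 3, ref), 0)
  expect_equal(standardize_npl(14, 3, ref), 1)
  expect_equal(standardize_npl(22, 5, ref), 3)
  expect_error(standardize_npl(5, 7, ref), "missing")
  expect_error(normative_reference(1:6, rep(0, 6), rep(0, 6)), "positive")

  expect_equal(composite_score(rep(0, 6), 1:6)$value, 0)
  expect_equal(composite_score(1:6, 1:6)$value, 21)
  partial <- composite_score(1:5, 1:5)
  expect_true(is.na(partial$value))
  expect_equal(partial$reason, "incomplete conditions")
})

test_that("composite_scores refuses attempts with a failed condition", {
  npl <- expand.grid(subject_id = c("A", "B"), attempt = 1:2,
                     condition = 1:6, stringsAsFactors = FALSE)
  npl$npl_ap <- 10
  npl <- npl[!(npl$subject_id == "B" & npl$attempt == 2 &
               npl$condition == 6), ]  # B's attempt 2 lost condition 6
  ref <- normative_reference(1:6, rep(10, 6), rep(4, 6))
  cs <- composite_scores(npl, ref)
  ok <- cs[cs$subject_id == "A", ]
  expect_true(all(ok$composite == 0))
  bad <- cs[cs$subject_id == "B" & cs$attempt == 2, ]
  expect_true(is.na(bad$composite))
  expect_equal(bad$reason, "incomplete conditions")
})

test_that("geometric mean CI matches closed forms and has ~95% coverage", {
  g <- geometric_mean_ci(rep(3, 5))
  expect_equal(c(g$gm, g$ci_low, g$ci_high), c(3, 3, 3))
  expect_equal(geometric_mean_ci(c(1, 100))$gm, 10)
  expect_error(geometric_mean_ci(c(1, -2)), "positive")
  g1 <- geometric_mean_ci(5)
  expect_equal(g1$gm, 5); expect_true(is.na(g1$ci_low))

  set.seed(14)
  big <- exp(rnorm(10000, mean = 2, sd = 0.5))
  expect_equal(geometric_mean_ci(big)$gm, exp(2), tolerance = 0.02)

  hits <- 0L; reps <- 1000L
  for (r in seq_len(reps)) {
    v <- exp(rnorm(40, mean = 2, sd = 0.5))
    ci <- geometric_mean_ci(v)
    hits <- hits + (ci$ci_low <= exp(2) && exp(2) <= ci$ci_high)
  }
  expect_gt(hits / reps, 0.93)
  expect_lt(hits / reps, 0.97)
})
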