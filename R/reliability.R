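#' Exclude facilitator-recorded failures and tally passes
#'
#' Removes from an NPL results table every trial flagged as a failure in the
#' manifest, and accounts for the protocol's pass pattern: per condition, how
#' many subjects passed both attempts, and overall how many subjects passed
#' both attempts of all six conditions. Failure flags are facilitator
#' observations of the subject's stance, so a failed attempt is failed for
#' every device recording it.
#'
#' @param results NPL results data frame (rows = trials; may span devices).
#' @param manifest A validated study manifest covering every result row.
#' @return List with `retained` (the filtered results) and `tally` (class
#'   `pass_fail_tally`).
#' @export
exclude_failures <- function(results, manifest) {
  manifest <- validate_manifest(as.data.frame(manifest))
  mkey <- paste(manifest$subject_id, manifest$device, manifest$condition,
                manifest$attempt, sep = "\r")
  rkey <- paste(results$subject_id, results$device, results$condition,
                results$attempt, sep = "\r")
  idx <- match(rkey, mkey)
  if (anyNA(idx))
    stop("results contain trials without a manifest entry, e.g.: ",
         gsub("\r", "/", rkey[which(is.na(idx))[1]]))
  retained <- results[!manifest$failed[idx], , drop = FALSE]
  if (nrow(retained) == 0)
    warning("all trials were flagged as failures; nothing retained")
  # pass accounting is per subject-condition-attempt (device-independent)
  sca <- unique(manifest[, c("subject_id", "condition", "attempt", "failed")])
  agg <- stats::aggregate(failed ~ subject_id + condition + attempt,
                          data = sca, FUN = any)
  both <- stats::aggregate(failed ~ subject_id + condition, data = agg,
                           FUN = function(f) !any(f))
  names(both)[3] <- "passed_both"
  per_cond <- stats::aggregate(passed_both ~ condition, data = both, FUN = sum)
  names(per_cond)[2] <- "n_passed_both"
  per_cond$n_total <- as.vector(table(both$condition)[
    as.character(per_cond$condition)])
  all_pass <- stats::aggregate(passed_both ~ subject_id, data = both,
                               FUN = all)
  reasons <- manifest$failure_reason[manifest$failed]
  tally <- structure(list(
    per_condition = per_cond,
    n_passed_all_conditions = sum(all_pass$passed_both),
    n_subjects = length(unique(manifest$subject_id)),
    n_failed_trials = sum(manifest$failed),
    failure_reasons = if (length(reasons)) table(reasons) else table(character())
  ), class = "pass_fail_tally")
  list(retained = retained, tally = tally)
}

#' @export
print.pass_fail_tally <- function(x, ...) {
  cat("Pass/fail tally over", x$n_subjects, "subjects\n")
  pc <- x$per_condition
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  condition %d: %d/%d passed both attempts\n",
                pc$condition[i], pc$n_passed_both[i], pc$n_total[i]))
  cat(sprintf("  all 6 conditions: %d/%d subjects\n",
              x$n_passed_all_conditions, x$n_subjects))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties). Returns `NA`
#' with a `"reason"` attribute when either input is constant (ranks
#' degenerate). No p-value is attached; inter-correlation inference is done
#' via [compare_correlations_fisher()].
#'
#' @param x,y Equal-length numeric vectors, length >= 3, no missing values.
#' @return Spearman's rho in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values; apply pairwise deletion upstream")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(x, y, method = "spearman")
}

#' Two-way random-effects single-measure intraclass correlation, ICC(2,1)
#'
#' Test-retest reliability of a measure over an n-subjects x k-measurements
#' matrix, under the two-way random-effects, absolute-agreement,
#' single-measure model. From the two-way ANOVA mean squares (rows = subjects
#' MSR, columns = measurements MSC, residual MSE):
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' The 95% CI follows the Shrout-Fleiss F-based procedure: with
#' `a = k*icc/(n*(1-icc))`, `b = 1 + k*icc*(n-1)/(n*(1-icc))`, the degrees of
#' freedom `v` of the F bound are the Satterthwaite combination
#' `v = (a*MSC + b*MSE)^2 / ((a*MSC)^2/(k-1) + (b*MSE)^2/((n-1)(k-1)))`, and
#' \deqn{L = \frac{n (MSR - F_{1-\alpha/2; n-1, v} MSE)}{F_{1-\alpha/2; n-1, v}
#'   (k MSC + (kn - k - n) MSE) + n MSR}}
#' with the upper bound obtained from `F_{1-alpha/2; v, n-1}` symmetrically.
#'
#' @param data Numeric n x k matrix, complete (no missing cells; no
#'   imputation is performed).
#' @param alpha Two-sided error rate for the CI (default 0.05).
#' @return An object of class `icc_estimate`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_measurements`, `mean_squares`, `alpha`. When the matrix
#'   has zero total variance the estimate is returned as `NA` with a
#'   `reason`.
#' @export
icc_2_1 <- function(data, alpha = 0.05) {
  data <- as.matrix(data)
  if (anyNA(data)) stop("missing cells in the ICC matrix; no imputation")
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 measurements")
  gm <- mean(data)
  if (all(data == data[1]))
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_subjects = n,
                          k_measurements = k, mean_squares = NULL,
                          alpha = alpha, reason = "zero total variance"),
                     class = "icc_estimate"))
  rowm <- rowMeans(data); colm <- colMeans(data)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((data - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # Shrout-Fleiss F-based CI (absolute agreement, single measure).
  # Perfect agreement (MSE = 0) makes the F bounds indeterminate; the CI
  # degenerates to the point estimate.
  if (mse == 0 || icc >= 1) {
    return(structure(list(icc = icc, ci_low = icc, ci_high = icc,
                          n_subjects = n, k_measurements = k,
                          mean_squares = c(MS_rows = msr, MS_cols = msc,
                                           MS_error = mse),
                          alpha = alpha, reason = NULL),
                     class = "icc_estimate"))
  }
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = lo, ci_high = hi, n_subjects = n,
                 k_measurements = k,
                 mean_squares = c(MS_rows = msr, MS_cols = msc, MS_error = mse),
                 alpha = alpha, reason = NULL),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  if (is.na(x$icc)) {
    cat("ICC(2,1): undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("ICC(2,1) = %.3f, %d%% CI %.3f-%.3f (n = %d subjects, k = %d)\n",
                x$icc, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
                x$n_subjects, x$k_measurements))
  }
  invisible(x)
}

#' Compare two independent correlations via Fisher's z-transformation
#'
#' Treats the two coefficients as Pearson correlations, applies
#' `z = atanh(rho)`, and compares with a standard normal procedure:
#' \deqn{z = \frac{\mathrm{atanh}(\rho_1) - \mathrm{atanh}(\rho_2)}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided normal p-value.
#'
#' @param rho_1,rho_2 Correlations, strictly inside (-1, 1).
#' @param n_1,n_2 Sample sizes (each >= 4).
#' @return An object of class `correlation_comparison`: the inputs plus
#'   `z_statistic` and `p_value`.
#' @export
compare_correlations_fisher <- function(rho_1, n_1, rho_2, n_2) {
  if (abs(rho_1) >= 1 || abs(rho_2) >= 1)
    stop("|rho| must be < 1 (Fisher transform is infinite at 1)")
  if (n_1 < 4 || n_2 < 4) stop("need n >= 4 in each sample")
  z <- (atanh(rho_1) - atanh(rho_2)) / sqrt(1 / (n_1 - 3) + 1 / (n_2 - 3))
  structure(list(rho_1 = rho_1, n_1 = n_1, rho_2 = rho_2, n_2 = n_2,
                 z_statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf(
    "Fisher-z comparison: rho1 = %.3f (n=%d) vs rho2 = %.3f (n=%d): z = %.3f, p = %.4g\n",
    x$rho_1, x$n_1, x$rho_2, x$n_2, x$z_statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Compares mean ranks across two or more groups with the standard
#' tie-corrected H statistic and a chi-square p-value on `groups - 1`
#' degrees of freedom. When every observation is identical the tie-correction
#' divisor vanishes; H is then defined as 0 with p = 1.
#'
#' @param groups List of numeric vectors, each non-empty, length >= 2.
#' @return List with `H`, `p_value`, `df`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1)
    return(list(H = 0, p_value = 1, df = length(groups) - 1L,
                n = length(values)))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter), n = length(values))
}

#' Anderson-Darling test of normality (estimated parameters)
#'
#' A-squared statistic against a normal distribution with mean and variance
#' estimated from the data (the composite-hypothesis case), with the small-
#' sample-adjusted p-value; `reject` flags departure from normality at the
#' 5% level. Location-scale transforms of the input leave the statistic
#' unchanged.
#'
#' @param values Numeric vector, n >= 8, non-constant.
#' @param alpha Rejection level (default 0.05).
#' @return List with `A2`, `p_value`, `reject`, `n`.
#' @export
anderson_darling_normal <- function(values, alpha = 0.05) {
  if (length(values) < 8) stop("Anderson-Darling needs n >= 8")
  if (stats::sd(values) == 0) stop("constant input: normality test undefined")
  at <- nortest::ad.test(values)
  list(A2 = unname(at$statistic), p_value = at$p.value,
       reject = at$p.value < alpha, n = length(values))
}
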