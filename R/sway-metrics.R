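#' Normalized path length of a one-dimensional sway series
#'
#' NPL is the cumulative absolute sample-to-sample change of the filtered
#' acceleration signal divided by the analyzed duration, in mG/sec; higher
#' values indicate more sway:
#' \deqn{NPL = \frac{1}{T} \sum_{i=2}^{N} |x_i - x_{i-1}|}
#' The denominator is elapsed analyzed time in seconds (not sample count), so
#' the result is rate-like and robust to minor truncation.
#'
#' @param x Numeric vector, filtered uniformly sampled acceleration in mG.
#' @param duration_s Analyzed duration in seconds.
#' @return NPL in mG/sec.
#' @examples
#' normalized_path_length(seq(0, 100, length.out = 2500), 50)  # ramp: 2 mG/sec
#' @export
normalized_path_length <- function(x, duration_s) {
  if (length(x) < 2) stop("NPL needs at least 2 samples")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  sum(abs(diff(x))) / duration_s
}

#' Total (three-axis) normalized path length
#'
#' NPL computed from the combined acceleration magnitude across all three
#' axes. The default `"path3d"` variant is the length of the path traced in
#' 3-D acceleration space per second: the per-step Euclidean norm of the
#' three-axis difference vector, summed and divided by duration. It is
#' translation-invariant with respect to the constant gravity offset. Two
#' alternatives are provided for comparison: `"magnitude"` (NPL of the
#' scalar magnitude series \eqn{\|a_i\|}, which is sensitive to the gravity
#' offset) and `"axis_norm"` (Euclidean norm of the vector of per-axis
#' NPLs).
#'
#' @param acc Numeric matrix, filtered 3-axis series (columns = axes), mG.
#' @param duration_s Analyzed duration in seconds.
#' @param variant One of `"path3d"` (default), `"magnitude"`, `"axis_norm"`.
#' @return Total NPL in mG/sec.
#' @export
total_npl <- function(acc, duration_s,
                      variant = c("path3d", "magnitude", "axis_norm")) {
  variant <- match.arg(variant)
  acc <- as.matrix(acc)
  if (nrow(acc) < 2) stop("NPL needs at least 2 samples")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  switch(variant,
    path3d = {
      d <- diff(acc)
      sum(sqrt(rowSums(d * d))) / duration_s
    },
    magnitude = normalized_path_length(sqrt(rowSums(acc * acc)), duration_s),
    axis_norm = sqrt(sum(apply(acc, 2, normalized_path_length,
                               duration_s = duration_s)^2))
  )
}

#' Compute the NPL metrics for one trial
#'
#' Runs the full metric chain on a single (non-failed) trial: trim the
#' initial transient, low-pass filter each axis, then compute AP NPL on the
#' convention-mapped anterior-posterior axis and total NPL over all three
#' axes. Failed trials are a contract error here; exclusion happens upstream
#' from the manifest.
#'
#' @param trial A [trial_recording()].
#' @param convention An [axis_convention()] for the trial's device; defaults
#'   to the device's entry in [default_conventions()].
#' @param trim A [trim_spec()].
#' @param filt A [filter_spec()].
#' @param total_variant Total-NPL variant, see [total_npl()].
#' @return A one-row data frame of class `npl_result` with columns
#'   `subject_id`, `device`, `condition`, `attempt`, `npl_ap`, `npl_total`,
#'   `duration_s`.
#' @export
trial_npl <- function(trial, convention = NULL, trim = trim_spec(),
                      filt = filter_spec(), total_variant = "path3d") {
  stopifnot(inherits(trial, "trial_recording"))
  if (trial$failed)
    stop("trial_npl was given a failed trial; exclude failures upstream")
  if (is.null(convention))
    convention <- attr(trial, "convention") %||%
      default_conventions()[[trial$device]]
  pp <- preprocess_trial(trial, trim, filt)
  dur <- attr(pp, "retained_duration_s")
  ap <- convention$ap$sign * pp$acc[, convention$ap$axis]
  res <- data.frame(
    subject_id = trial$subject_id, device = trial$device,
    condition = trial$condition, attempt = trial$attempt,
    npl_ap = normalized_path_length(ap, dur),
    npl_total = total_npl(pp$acc, dur, variant = total_variant),
    duration_s = dur, stringsAsFactors = FALSE)
  class(res) <- c("npl_result", "data.frame")
  res
}

#' Normative reference for standardizing NPL
#'
#' Per-condition location and scale used to turn an NPL value into a
#' dimensionless standardized score. The package ships no population
#' normative table; build one from your own reference sample or from the
#' simulator (see [build_reference_from_npl()]), in which case it is
#' synthetic and must not be interpreted normatively.
#'
#' @param condition Integer vector of conditions (1..6).
#' @param location,scale Numeric vectors, per-condition mG/sec (or log
#'   mG/sec when `log_scale`).
#' @param log_scale If `TRUE`, standardization is applied to `log(NPL)`.
#' @return A data frame of class `normative_reference`.
#' @export
normative_reference <- function(condition, location, scale,
                                log_scale = FALSE) {
  stopifnot(length(condition) == length(location),
            length(condition) == length(scale))
  if (any(scale <= 0)) stop("reference scale must be positive")
  if (anyDuplicated(condition)) stop("duplicate conditions in reference")
  ref <- data.frame(condition = as.integer(condition),
                    location = location, scale = scale)
  attr(ref, "log_scale") <- isTRUE(log_scale)
  class(ref) <- c("normative_reference", "data.frame")
  ref
}

#' Build a reference table from an NPL results table
#'
#' Convenience: per-condition mean and SD of (optionally log) AP NPL over a
#' reference sample of non-failed trials.
#'
#' @param npl Data frame of NPL results (one row per trial).
#' @param metric Column to standardize, `"npl_ap"` (default) or `"npl_total"`.
#' @param log_scale Standardize on the log scale.
#' @return A [normative_reference()].
#' @export
build_reference_from_npl <- function(npl, metric = "npl_ap",
                                     log_scale = FALSE) {
  v <- npl[[metric]]
  if (log_scale) v <- log(v)
  agg_m <- tapply(v, npl$condition, mean)
  agg_s <- tapply(v, npl$condition, stats::sd)
  normative_reference(as.integer(names(agg_m)), as.numeric(agg_m),
                      as.numeric(agg_s), log_scale = log_scale)
}

#' Standardize an NPL value against a normative reference
#'
#' Returns `(value - location_c) / scale_c` for the value's condition, on the
#' raw or log scale per the reference's flag.
#'
#' @param value NPL in mG/sec (vectorized).
#' @param condition Condition 1..6 (recycled against `value`).
#' @param ref A [normative_reference()].
#' @return Dimensionless standardized value(s).
#' @export
standardize_npl <- function(value, condition, ref) {
  stopifnot(inherits(ref, "normative_reference"))
  idx <- match(condition, ref$condition)
  if (anyNA(idx))
    stop("condition(s) missing from the normative reference: ",
         paste(unique(condition[is.na(idx)]), collapse = ", "))
  v <- if (isTRUE(attr(ref, "log_scale"))) log(value) else value
  (v - ref$location[idx]) / ref$scale[idx]
}

#' Composite balance score for one subject-attempt
#'
#' The composite score is the sum of the standardized NPL values across all
#' six protocol conditions. It is defined only when all six conditions are
#' present and non-failed; partial composites are refused rather than
#' rescaled.
#'
#' @param std_values Named or ordered numeric vector of standardized values.
#' @param conditions Integer vector of the conditions contributing (same
#'   length as `std_values`).
#' @return A list of class `composite_score` with `value` (the sum, or `NA`)
#'   and `reason` (`NULL` when defined).
#' @export
composite_score <- function(std_values, conditions = seq_along(std_values)) {
  conditions <- as.integer(conditions)
  if (!setequal(conditions, 1:6) || length(conditions) != 6 ||
      anyNA(std_values)) {
    return(structure(list(value = NA_real_, conditions = conditions,
                          reason = "incomplete conditions"),
                     class = "composite_score"))
  }
  structure(list(value = sum(std_values), conditions = 1:6, reason = NULL),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  if (is.na(x$value))
    cat("Composite score: undefined (", x$reason, ")\n", sep = "")
  else cat(sprintf("Composite score: %.3f (6 conditions)\n", x$value))
  invisible(x)
}

#' Composite scores for every subject-attempt in an NPL table
#'
#' Standardizes the chosen metric against `ref` and sums across conditions
#' per (subject, attempt). Attempts missing any of the six conditions (e.g.
#' through failure exclusion) get `NA` with reason "incomplete conditions".
#'
#' @param npl NPL results table (rows = retained trials, one device).
#' @param ref A [normative_reference()].
#' @param metric `"npl_ap"` (default) or `"npl_total"`.
#' @return Data frame with `subject_id`, `attempt`, `composite`, `reason`.
#' @export
composite_scores <- function(npl, ref, metric = "npl_ap") {
  npl$z <- standardize_npl(npl[[metric]], npl$condition, ref)
  keys <- unique(npl[, c("subject_id", "attempt")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- npl$subject_id == keys$subject_id[i] & npl$attempt == keys$attempt[i]
    cs <- composite_score(npl$z[sel], npl$condition[sel])
    data.frame(subject_id = keys$subject_id[i], attempt = keys$attempt[i],
               composite = cs$value,
               reason = cs$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Geometric mean with a t-based 95% confidence interval
#'
#' Per-condition NPL distributions are right-skewed, so condition summaries
#' are reported as geometric means: `gm = exp(mean(log x))`, with the CI the
#' exponential of the t-based CI of the log-mean.
#'
#' @param values Positive numeric vector.
#' @param alpha Two-sided error rate (default 0.05).
#' @return List with `gm`, `ci_low`, `ci_high`, `n`. For `n = 1` the CI is
#'   `NA`.
#' @export
geometric_mean_ci <- function(values, alpha = 0.05) {
  if (any(values <= 0)) stop("geometric mean requires positive values")
  n <- length(values)
  lx <- log(values)
  gm <- exp(mean(lx))
  if (n < 2) return(list(gm = gm, ci_low = NA_real_, ci_high = NA_real_, n = n))
  half <- stats::qt(1 - alpha / 2, df = n - 1) * stats::sd(lx) / sqrt(n)
  list(gm = gm, ci_low = exp(mean(lx) - half), ci_high = exp(mean(lx) + half),
       n = n)
}
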