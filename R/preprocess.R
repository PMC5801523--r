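#' Low-pass filter specification
#'
#' The preprocessing filter applied to every accelerometer axis before sway
#' metrics are computed: a fourth-order Butterworth low-pass with a 1.25 Hz
#' cutoff, applied as a single causal pass by default. The digital design
#' uses the bilinear transform with cutoff prewarping, so the -3 dB point of
#' the realized filter sits exactly at `cutoff_hz`. Setting
#' `zero_phase = TRUE` applies the filter forward and backward
#' (which removes phase lag but doubles the effective order).
#'
#' @param order Filter order (default 4).
#' @param cutoff_hz Cutoff frequency in Hz (default 1.25).
#' @param zero_phase Forward-backward application (default `FALSE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 1.25, zero_phase = FALSE) {
  stopifnot(order >= 1, order == round(order), cutoff_hz > 0)
  structure(list(family = "butterworth", kind = "lowpass",
                 order = as.integer(order), cutoff_hz = cutoff_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Initial-transient trim specification
#'
#' The first `discard_seconds` of every trial are discarded to ensure
#' stability of the measures: of a nominal 60 s stance, the final 50 s are
#' analyzed.
#'
#' @param discard_seconds Seconds removed from the start (default 10).
#' @param expected_trial_seconds Nominal full trial length (default 60);
#'   shorter retained spans trigger a warning, not an error.
#' @return An object of class `trim_spec`.
#' @export
trim_spec <- function(discard_seconds = 10, expected_trial_seconds = 60) {
  stopifnot(discard_seconds >= 0, expected_trial_seconds > 0,
            discard_seconds < expected_trial_seconds)
  structure(list(discard_seconds = discard_seconds,
                 expected_trial_seconds = expected_trial_seconds),
            class = "trim_spec")
}

#' Butterworth coefficients for a filter spec at a sampling rate
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; must exceed twice the cutoff.
#' @return List with numerator `b` and denominator `a` of the digital filter.
#' @export
butter_coefficients <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$cutoff_hz >= fs / 2)
    stop(sprintf("cutoff %.3g Hz is at or above Nyquist (%.3g Hz)",
                 spec$cutoff_hz, fs / 2))
  ba <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  list(b = as.numeric(ba$b), a = as.numeric(ba$a))
}

#' Magnitude response of the realized digital filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| from the designed coefficients; used to
#' verify the -3 dB placement and stop-band attenuation of the implemented
#' filter.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz.
#' @param freqs_hz Frequencies at which to evaluate, in Hz.
#' @return Numeric vector of gains (same length as `freqs_hz`).
#' @export
filter_response <- function(spec, fs, freqs_hz) {
  ba <- butter_coefficients(spec, fs)
  vapply(freqs_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(ba$b * z^(seq_along(ba$b) - 1)) /
        sum(ba$a * z^(seq_along(ba$a) - 1)))
  }, numeric(1))
}

#' Discard the initial seconds of a trial
#'
#' Removes all samples with elapsed time (from the first timestamp) strictly
#' below `spec$discard_seconds`. Sample values are never altered, only
#' membership. Warns when the retained span is shorter than the expected
#' analyzed duration.
#'
#' @param trial A [trial_recording()].
#' @param spec A [trim_spec()].
#' @return The trimmed [trial_recording()], with attribute
#'   `"retained_duration_s"`.
#' @export
trim_initial <- function(trial, spec = trim_spec()) {
  stopifnot(inherits(trial, "trial_recording"), inherits(spec, "trim_spec"))
  elapsed <- (trial$timestamps_ms - trial$timestamps_ms[1]) / 1000
  dur <- trial_duration_s(trial)
  if (dur <= spec$discard_seconds)
    stop(sprintf(
      "no analyzable data: trial spans %.2f s, discard is %g s",
      dur, spec$discard_seconds))
  keep <- elapsed >= spec$discard_seconds
  out <- trial
  out$timestamps_ms <- trial$timestamps_ms[keep]
  out$acc <- trial$acc[keep, , drop = FALSE]
  retained <- trial_duration_s(out)
  expected <- spec$expected_trial_seconds - spec$discard_seconds
  # nominal grids end one sample short of the full span (e.g. 59.98 s at
  # 50 Hz); only flag spans short by more than one sample period
  if (retained < expected - 1.5 / trial$sample_rate_hz)
    warning(sprintf(
      "retained duration %.2f s is shorter than the expected %.2f s",
      retained, expected))
  attr(out, "retained_duration_s") <- retained
  out
}

#' Low-pass filter a uniformly sampled series
#'
#' Applies the Butterworth low-pass of `spec` to a numeric vector, or to each
#' column of a matrix independently. Single causal pass by default;
#' forward-backward when `spec$zero_phase`.
#'
#' The filter state is initialized at the DC steady state of the signal's
#' first sample (the `lfilter_zi`/`filtic` idiom), so a constant input passes
#' through unchanged and the constant gravity offset on the vertical axis
#' contributes no start-up transient to the path-length metrics. This
#' initialization keeps the operation linear and leaves the frequency
#' response untouched.
#'
#' @param x Numeric vector or matrix (columns = axes), uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, spec = filter_spec()) {
  ba <- butter_coefficients(spec, fs)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (n < 3 * spec$order)
    stop(sprintf("signal too short to filter: %d samples < 3*order = %d",
                 n, 3L * spec$order))
  arma <- structure(list(b = ba$b, a = ba$a), class = "Arma")
  f1 <- function(v) {
    # DC-matched initial state: filter the deviation from the first sample
    # with zero state and add the offset back (unity DC gain)
    if (spec$zero_phase) v[1] + as.numeric(signal::filtfilt(arma, v - v[1]))
    else v[1] + as.numeric(signal::filter(arma, v - v[1]))
  }
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- f1(x[, j])
    out
  } else f1(x)
}

#' Trim and filter one trial
#'
#' The standard preprocessing chain: discard the initial transient, then
#' low-pass filter each axis independently. Metadata (subject, device,
#' condition, attempt, failure flags) is preserved; the retained analyzed
#' duration is available as the `"retained_duration_s"` attribute.
#'
#' @param trial A [trial_recording()].
#' @param trim A [trim_spec()].
#' @param filt A [filter_spec()].
#' @return The preprocessed [trial_recording()].
#' @export
preprocess_trial <- function(trial, trim = trim_spec(), filt = filter_spec()) {
  trimmed <- trim_initial(trial, trim)
  out <- trimmed
  out$acc <- lowpass_filter(trimmed$acc, trial$sample_rate_hz, filt)
  attr(out, "retained_duration_s") <- attr(trimmed, "retained_duration_s")
  out
}
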