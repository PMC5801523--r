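#' Configuration for a synthetic two-device balance study
#'
#' Defines the generative model for a synthetic standing-balance study with
#' head- and waist-mounted accelerometers. For subject j, condition c,
#' attempt t, the latent log sway amplitude is
#' `L = baseline_log_amp + log(g_c) + u_j + e_{jct}` with
#' `u_j ~ N(0, subject_sd^2)` and `e ~ N(0, attempt_sd^2)`; the head device
#' additionally carries `log(head_gain)`. Latent deviations are bivariate
#' normal across devices with correlation `device_coupling`, and each trial's
#' sway realization mixes a shared band-limited process with weight
#' `sqrt(device_coupling)`, so at coupling 1 (and equal gains, zero noise)
#' the two devices record identical signals. Anterior-posterior sway is a
#' band-limited Gaussian process (white noise shaped by a second-order
#' low-pass at `sway_bandwidth_hz`) scaled to RMS `exp(L)`; mediolateral and
#' vertical axes carry attenuated independent processes driven by the same
#' latent amplitude; the vertical axis carries a constant 1000 mG gravity
#' offset; white sensor noise is added per axis.
#'
#' @param n_subjects Number of subjects (default 42).
#' @param n_attempts Attempts per condition (1 or 2; default 2).
#' @param sample_rate_hz Sampling rate (default 50).
#' @param trial_seconds Trial length in seconds (default 60).
#' @param baseline_log_amp Baseline log RMS sway amplitude, log mG
#'   (default `log(5)`).
#' @param condition_gains Positive multiplicative sway gains for conditions
#'   1..6; the default increases from the easiest stance (firm surface, feet
#'   together, eyes open) to the hardest (tandem, eyes closed), with each
#'   eyes-closed condition above its eyes-open pair.
#' @param subject_sd Between-subject SD of the latent log amplitude.
#' @param attempt_sd Within-subject (attempt-to-attempt) SD.
#' @param head_gain Multiplicative head amplitude gain (default 1.3; head
#'   sway is generally larger than waist sway).
#' @param device_coupling Correlation of latent log amplitudes (and shared
#'   fraction of the sway realization) between devices, in `[0, 1]`.
#' @param sway_bandwidth_hz Bandwidth of the sway process (default 0.5).
#' @param ml_ratio,vert_ratio Amplitude of the mediolateral / vertical sway
#'   relative to AP (defaults 0.5 and 0.2).
#' @param sensor_noise_sd White sensor noise SD per axis, mG (default 2).
#' @param failure_prob Per-condition probability that the facilitator fails
#'   one attempt; defaults mimic the protocol's typical pass pattern (no
#'   failures on conditions 1-3, occasional on 4-5, frequent on tandem
#'   eyes-closed).
#' @param seed Integer seed; every random draw in the simulation flows from
#'   it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 42, n_attempts = 2,
                              sample_rate_hz = 50, trial_seconds = 60,
                              baseline_log_amp = log(5),
                              condition_gains = c(1, 1.65, 1.9, 3.15, 3.65, 6.05),
                              subject_sd = 0.6, attempt_sd = 0.25,
                              head_gain = 1.3, device_coupling = 0.9,
                              sway_bandwidth_hz = 0.5,
                              ml_ratio = 0.5, vert_ratio = 0.2,
                              sensor_noise_sd = 2,
                              failure_prob = c(0, 0, 0, 0.062, 0.012, 0.155),
                              seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!n_attempts %in% 1:2) stop("n_attempts must be 1 or 2")
  if (length(condition_gains) != 6 || any(condition_gains <= 0))
    stop("condition_gains must be 6 positive values")
  if (subject_sd < 0 || attempt_sd < 0 || sensor_noise_sd < 0)
    stop("standard deviations must be >= 0")
  if (device_coupling < 0 || device_coupling > 1)
    stop("device_coupling must be in [0, 1]")
  if (head_gain <= 0) stop("head_gain must be positive")
  if (length(failure_prob) != 6 || any(failure_prob < 0 | failure_prob > 1))
    stop("failure_prob must be 6 probabilities")
  if (sway_bandwidth_hz <= 0 || sway_bandwidth_hz >= sample_rate_hz / 2)
    stop("sway_bandwidth_hz must be in (0, Nyquist)")
  if (trial_seconds <= 0 || sample_rate_hz <= 0)
    stop("trial_seconds and sample_rate_hz must be positive")
  structure(list(
    n_subjects = as.integer(n_subjects), n_attempts = as.integer(n_attempts),
    sample_rate_hz = sample_rate_hz, trial_seconds = trial_seconds,
    baseline_log_amp = baseline_log_amp, condition_gains = condition_gains,
    subject_sd = subject_sd, attempt_sd = attempt_sd, head_gain = head_gain,
    device_coupling = device_coupling, sway_bandwidth_hz = sway_bandwidth_hz,
    ml_ratio = ml_ratio, vert_ratio = vert_ratio,
    sensor_noise_sd = sensor_noise_sd, failure_prob = failure_prob,
    seed = as.integer(seed), protocol = bam_protocol(trial_seconds)
  ), class = "simulation_config")
}

# Unit-SD band-limited Gaussian process: white noise shaped by a 2nd-order
# Butterworth low-pass, with a 12 s burn-in dropped so the filter state is
# stationary, then centered and scaled to exact unit sample SD.
.band_limited <- function(n, fs, bw_hz) {
  burn <- ceiling(12 * fs)
  ba <- signal::butter(2, bw_hz / (fs / 2), type = "low")
  y <- as.numeric(signal::filter(ba, stats::rnorm(n + burn)))
  y <- y[(burn + 1):(burn + n)]
  (y - mean(y)) / stats::sd(y)
}

# All per-trial-slot signal randomness (shared + per-device processes and
# sensor noise for both devices) is drawn under the slot's own seed, in a
# fixed order, so a slot's signals are identical whether the study is
# materialized or streamed.
.slot_signals <- function(slot_seed, config) {
  set.seed(slot_seed)
  n <- round(config$trial_seconds * config$sample_rate_hz)
  fs <- config$sample_rate_hz
  bw <- config$sway_bandwidth_hz
  cpl <- config$device_coupling
  mix <- function() {
    s0 <- .band_limited(n, fs, bw)
    dw <- .band_limited(n, fs, bw)
    dh <- .band_limited(n, fs, bw)
    std <- function(v) (v - mean(v)) / stats::sd(v)
    list(waist = std(sqrt(cpl) * s0 + sqrt(1 - cpl) * dw),
         head = std(sqrt(cpl) * s0 + sqrt(1 - cpl) * dh))
  }
  out <- list(ap = mix(), ml = mix(), vert = mix())
  out$noise <- list(
    waist = matrix(stats::rnorm(3 * n, 0, config$sensor_noise_sd), ncol = 3),
    head = matrix(stats::rnorm(3 * n, 0, config$sensor_noise_sd), ncol = 3))
  out
}

# Assemble one device's acc matrix from the slot signals and latent amplitude.
.assemble_acc <- function(sig, device, log_amp, config, convention) {
  n <- length(sig$ap[[device]])
  amp <- exp(log_amp)
  acc <- matrix(0, nrow = n, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  put <- function(axspec, values) {
    acc[, axspec$axis] <<- acc[, axspec$axis] + axspec$sign * values
  }
  put(convention$ap, amp * sig$ap[[device]])
  put(convention$ml, config$ml_ratio * amp * sig$ml[[device]])
  put(convention$vertical, 1000 + config$vert_ratio * amp * sig$vert[[device]])
  acc + sig$noise[[device]]
}

#' Simulate a synthetic two-device balance study
#'
#' Generates every trial of a study under the model described in
#' [simulation_config()]. With `output = "recordings"` the full
#' [trial_recording()] objects are returned (memory-heavy at scale); with
#' `output = "npl"` each trial is pushed through the standard preprocessing
#' and NPL chain as it is generated and only the per-trial NPL table is kept,
#' which is the practical path for large parameter-recovery runs. Identical
#' seeds produce identical studies under either output mode.
#'
#' @param config A [simulation_config()].
#' @param output `"recordings"` or `"npl"`.
#' @param conventions Axis conventions per device (default
#'   [default_conventions()]).
#' @param trim,filt,total_variant Preprocessing and metric settings used when
#'   `output = "npl"`; `trim` defaults to a [trim_spec()] whose expected trial
#'   length is the configured `trial_seconds`.
#' @return A list with elements `manifest` (in-memory manifest, `file = NA`),
#'   `truth` (per-trial latent log amplitudes and failure flags), and either
#'   `trials` (list of recordings) or `npl` (NPL results for non-failed
#'   trials).
#' @export
simulate_study <- function(config = simulation_config(),
                           output = c("recordings", "npl"),
                           conventions = default_conventions(),
                           trim = NULL, filt = filter_spec(),
                           total_variant = "path3d") {
  stopifnot(inherits(config, "simulation_config"))
  output <- match.arg(output)
  if (is.null(trim))
    trim <- trim_spec(expected_trial_seconds = config$trial_seconds)
  ns <- config$n_subjects; na <- config$n_attempts
  subjects <- sprintf("S%02d", seq_len(ns))
  # slot = one (subject, condition, attempt); both devices share a slot
  slots <- expand.grid(attempt = seq_len(na), condition = 1:6,
                       subject = seq_len(ns))[, c("subject", "condition",
                                                  "attempt")]
  nslot <- nrow(slots)

  set.seed(config$seed)
  # latent effects: bivariate across devices with correlation = coupling
  rho <- config$device_coupling
  z1 <- stats::rnorm(ns); z2 <- stats::rnorm(ns)
  u_w <- config$subject_sd * z1
  u_h <- config$subject_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  w1 <- stats::rnorm(nslot); w2 <- stats::rnorm(nslot)
  e_w <- config$attempt_sd * w1
  e_h <- config$attempt_sd * (rho * w1 + sqrt(1 - rho^2) * w2)
  fail_u <- stats::runif(nslot)
  failed <- fail_u < config$failure_prob[slots$condition]
  reason_pick <- sample(c("feet_moved", "arms_off_chest"), nslot,
                        replace = TRUE)
  slot_seeds <- sample.int(.Machine$integer.max - 1L, nslot)

  log_g <- log(config$condition_gains)[slots$condition]
  L_w <- config$baseline_log_amp + log_g + u_w[slots$subject] + e_w
  L_h <- config$baseline_log_amp + log(config$head_gain) + log_g +
    u_h[slots$subject] + e_h

  ts <- (seq_len(round(config$trial_seconds * config$sample_rate_hz)) - 1) *
    (1000 / config$sample_rate_hz)

  manifest <- truth <- vector("list", 2 * nslot)
  trials <- if (output == "recordings") vector("list", 2 * nslot) else NULL
  npl <- if (output == "npl") vector("list", 2 * nslot) else NULL

  for (i in seq_len(nslot)) {
    sig <- .slot_signals(slot_seeds[i], config)
    sj <- subjects[slots$subject[i]]
    for (device in c("waist", "head")) {
      L <- if (device == "waist") L_w[i] else L_h[i]
      k <- 2 * (i - 1) + if (device == "waist") 1L else 2L
      acc <- .assemble_acc(sig, device, L, config, conventions[[device]])
      reason <- if (failed[i]) reason_pick[i] else NULL
      tr <- trial_recording(sj, device, slots$condition[i], slots$attempt[i],
                            ts, acc, sample_rate_hz = config$sample_rate_hz,
                            failed = failed[i], failure_reason = reason)
      attr(tr, "convention") <- conventions[[device]]
      manifest[[k]] <- data.frame(
        file = NA_character_, subject_id = sj, device = device,
        condition = slots$condition[i], attempt = slots$attempt[i],
        failed = failed[i], failure_reason = reason %||% NA_character_,
        stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        subject_id = sj, device = device, condition = slots$condition[i],
        attempt = slots$attempt[i], log_amp = L, failed = failed[i],
        stringsAsFactors = FALSE)
      if (output == "recordings") {
        trials[[k]] <- tr
      } else if (!failed[i]) {
        npl[[k]] <- trial_npl(tr, conventions[[device]], trim, filt,
                              total_variant)
      }
    }
  }
  manifest <- validate_manifest(do.call(rbind, manifest))
  truth <- do.call(rbind, truth)
  attr(truth, "config") <- config
  out <- list(manifest = manifest, truth = truth)
  if (output == "recordings") out$trials <- trials
  else out$npl <- do.call(rbind, npl[!vapply(npl, is.null, logical(1))])
  out
}

#' Ground-truth condition ordering implied by a configuration
#'
#' Conditions sorted by their designed sway gain, the ordering that condition
#' -effect recovery tests check against (each eyes-closed condition should
#' rank above its eyes-open pair under the defaults).
#'
#' @param config A [simulation_config()].
#' @return Integer vector of condition indices in increasing-gain order, with
#'   attribute `"tied"` = `TRUE` when two conditions share a gain.
#' @export
expected_condition_ordering <- function(config = simulation_config()) {
  g <- config$condition_gains
  structure(order(g), tied = anyDuplicated(g) > 0)
}

#' Write a synthetic study to disk as trial files plus manifest
#'
#' Materializes a simulated study in the package's CSV dialect: one trial
#' file per (subject, device, condition, attempt) and a `manifest.csv`
#' indexing them. `"tiny"` (4 subjects, 96 trials) is sized for fast tests;
#' `"paper_scale"` (42 subjects, 1008 trials) matches the study design the
#' generator emulates.
#'
#' @param dir Output directory (created if needed).
#' @param size `"tiny"` or `"paper_scale"`.
#' @param seed Integer seed.
#' @param config Optional [simulation_config()] overriding `size`/`seed`.
#' @return Invisibly, the manifest path.
#' @export
make_fixture_study <- function(dir, size = c("tiny", "paper_scale"),
                               seed = 1L, config = NULL) {
  size <- match.arg(size)
  if (is.null(config))
    config <- simulation_config(
      n_subjects = if (size == "tiny") 4L else 42L, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_study(config, output = "recordings")
  m <- as.data.frame(sim$manifest)
  for (k in seq_along(sim$trials)) {
    tr <- sim$trials[[k]]
    fname <- sprintf("%s_%s_c%d_a%d.csv", tr$subject_id, tr$device,
                     tr$condition, tr$attempt)
    write_trial_csv(tr, file.path(dir, fname))
    m$file[k] <- fname
  }
  path <- file.path(dir, "manifest.csv")
  write_manifest(m, path)
  invisible(path)
}
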