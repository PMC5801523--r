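#' Construct a trial recording
#'
#' A `trial_recording` holds one 60 s, three-axis accelerometer recording for
#' a (subject, device, condition, attempt) cell, in milli-g (mG), together
#' with its elapsed timestamps in milliseconds and failure metadata.
#'
#' @param subject_id Subject identifier (character).
#' @param device `"head"` or `"waist"`.
#' @param condition Integer stance condition, 1-6.
#' @param attempt Integer attempt number, 1-2.
#' @param timestamps_ms Strictly increasing numeric vector, elapsed ms from
#'   trial start.
#' @param acc Numeric matrix with one row per sample and columns `x`, `y`,
#'   `z`, in mG.
#' @param sample_rate_hz Nominal sampling rate; if `NULL`, inferred from the
#'   median timestamp spacing.
#' @param failed Logical failure flag (facilitator-recorded).
#' @param failure_reason Optional reason code, one of [failure_reasons()].
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, device, condition, attempt,
                            timestamps_ms, acc, sample_rate_hz = NULL,
                            failed = FALSE, failure_reason = NULL) {
  device <- match.arg(device, c("head", "waist"))
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("acc must have 3 columns (x, y, z)")
  colnames(acc) <- c("x", "y", "z")
  timestamps_ms <- as.numeric(timestamps_ms)
  if (length(timestamps_ms) != nrow(acc))
    stop("timestamps and acc must have the same number of samples")
  if (length(timestamps_ms) > 1 && any(diff(timestamps_ms) <= 0))
    stop("timestamps must be strictly increasing")
  if (length(acc) && !all(is.finite(acc)))
    stop("acc values must be finite")
  condition <- as.integer(condition)
  attempt <- as.integer(attempt)
  if (!condition %in% 1:6) stop("condition must be in 1..6")
  if (!attempt %in% 1:2) stop("attempt must be in 1..2")
  if (is.null(sample_rate_hz)) {
    if (length(timestamps_ms) < 2) stop("cannot infer sample rate from < 2 samples")
    sample_rate_hz <- 1000 / stats::median(diff(timestamps_ms))
  }
  if (!is.null(failure_reason) && !failure_reason %in% failure_reasons())
    stop("unknown failure_reason: ", failure_reason)
  structure(list(
    subject_id = as.character(subject_id), device = device,
    condition = condition, attempt = attempt,
    sample_rate_hz = as.numeric(sample_rate_hz),
    timestamps_ms = timestamps_ms, acc = acc,
    failed = isTRUE(failed), failure_reason = failure_reason
  ), class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  dur <- if (length(x$timestamps_ms) > 1)
    diff(range(x$timestamps_ms)) / 1000 else 0
  cat(sprintf(
    "Trial recording: subject %s, %s device, condition %d, attempt %d\n",
    x$subject_id, x$device, x$condition, x$attempt))
  cat(sprintf("  %d samples, %.2f s at %.1f Hz (nominal)%s\n",
              nrow(x$acc), dur, x$sample_rate_hz,
              if (x$failed) paste0("  [FAILED: ",
                                   x$failure_reason %||% "unspecified", "]")
              else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trial duration in seconds
#' @param trial A [trial_recording()].
#' @return Elapsed seconds between the first and last timestamp.
#' @export
trial_duration_s <- function(trial) {
  if (length(trial$timestamps_ms) < 2) return(0)
  diff(range(trial$timestamps_ms)) / 1000
}

# The on-disk dialect: header `timestamp_ms,ax,ay,az[,gx,gy,gz]`, comma
# separator, '.' decimal, no quoting, values in mG. Gyroscope columns are
# accepted and dropped (recorded by the devices but never analyzed).
.trial_header <- c("timestamp_ms", "ax", "ay", "az")

#' Read a trial recording from its comma-delimited file
#'
#' Parses one time-stamped accelerometer trial file as stored by the capture
#' devices: a header row `timestamp_ms,ax,ay,az` (optionally followed by
#' `gx,gy,gz`, which are ignored), then one row per sample. Acceleration is
#' in mG, timestamps in elapsed milliseconds.
#'
#' @param path Path to the trial file.
#' @param meta A list or one-row data frame with fields `subject_id`,
#'   `device`, `condition`, `attempt` and optionally `failed`,
#'   `failure_reason`.
#' @param convention An [axis_convention()]; attached to the recording as the
#'   `"convention"` attribute (axes are stored as recorded, unmapped).
#' @return A [trial_recording()].
#' @export
read_trial_csv <- function(path, meta, convention = NULL) {
  if (!file.exists(path)) stop("no such trial file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(lines)))
    stop("empty trial file: ", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (length(header) < 4 || !identical(header[1:4], .trial_header))
    stop("bad header in ", path, ": expected 'timestamp_ms,ax,ay,az'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("trial file has no data rows: ", path)
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 4)) {
    bad <- which(nfield < 4)[1]
    stop(sprintf("malformed row at line %d of %s: fewer than 4 fields",
                 bad + 1L, path))
  }
  num <- matrix(NA_real_, nrow = length(parts), ncol = 4)
  for (j in 1:4) {
    col <- vapply(parts, `[[`, "", j)
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("malformed row at line %d of %s: non-numeric '%s' in %s",
                   bad + 1L, path, col[bad], .trial_header[j]))
    }
    num[, j] <- v
  }
  ts <- num[, 1]
  if (any(diff(ts) <= 0))
    stop("non-monotone timestamps in ", path)
  meta <- as.list(meta)
  tr <- trial_recording(
    subject_id = meta$subject_id, device = meta$device,
    condition = meta$condition, attempt = meta$attempt,
    timestamps_ms = ts, acc = num[, 2:4, drop = FALSE],
    failed = isTRUE(as.logical(meta$failed %||% FALSE)),
    failure_reason = if (is.null(meta$failure_reason) ||
                         is.na(meta$failure_reason) ||
                         !nzchar(meta$failure_reason)) NULL
                     else as.character(meta$failure_reason)
  )
  if (!is.null(convention)) attr(tr, "convention") <- convention
  tr
}

#' Write a trial recording in the package's comma-delimited dialect
#'
#' Emits exactly the dialect [read_trial_csv()] accepts, at full double
#' precision (`%.17g`), so write-then-read is the identity and two writes of
#' the same trial are byte-identical.
#'
#' @param trial A [trial_recording()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  if (nrow(trial$acc) == 0)
    stop("refusing to write a trial with 0 samples")
  rows <- sprintf("%.17g,%.17g,%.17g,%.17g",
                  trial$timestamps_ms, trial$acc[, 1], trial$acc[, 2],
                  trial$acc[, 3])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(.trial_header, collapse = ","), rows), con, sep = "\n")
  invisible(path)
}

#' Convert acceleration from m/s^2 to milli-g
#'
#' NPL is reported in mG/sec; sensors that report SI units are converted with
#' `out = in / 9.80665 * 1000` (standard gravity).
#'
#' @param values Numeric vector/matrix in m/s^2.
#' @return Values in mG.
#' @examples
#' convert_to_milli_g(9.80665)  # 1000 mG
#' @export
convert_to_milli_g <- function(values) {
  if (!all(is.finite(values))) stop("non-finite acceleration values")
  values / 9.80665 * 1000
}

#' Convert milli-g back to m/s^2
#' @param values Numeric vector/matrix in mG.
#' @return Values in m/s^2.
#' @export
convert_from_milli_g <- function(values) {
  if (!all(is.finite(values))) stop("non-finite acceleration values")
  values * 9.80665 / 1000
}

#' Resample a trial onto a uniform grid
#'
#' Device timestamps jitter around the nominal 50 Hz grid; this linearly
#' interpolates each axis onto a uniform grid at `target_hz` spanning the
#' recorded time range. Constant and affine signals are reproduced exactly.
#'
#' @param trial A [trial_recording()].
#' @param target_hz Target sampling rate in Hz.
#' @return A [trial_recording()] on the uniform grid with
#'   `sample_rate_hz = target_hz`.
#' @export
regularize_sampling <- function(trial, target_hz = 50) {
  stopifnot(inherits(trial, "trial_recording"), target_hz > 0)
  ts <- trial$timestamps_ms
  if (length(ts) < 2) stop("need at least 2 samples to resample")
  grid <- seq(ts[1], ts[length(ts)], by = 1000 / target_hz)
  if (length(grid) < 2)
    stop("recorded span too short for the target rate")
  acc <- apply(trial$acc, 2, function(col)
    stats::approx(ts, col, xout = grid, method = "linear")$y)
  out <- trial
  out$timestamps_ms <- grid
  out$acc <- matrix(acc, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  out$sample_rate_hz <- target_hz
  out
}

#' Read a study manifest
#'
#' A manifest lists every trial of a study: one row per (subject, device,
#' condition, attempt) with the trial file path and the facilitator's failure
#' flag. Accepted as CSV (columns `file`, `subject_id`, `device`,
#' `condition`, `attempt`, `failed`, `failure_reason`) or as a YAML list of
#' entries with those fields.
#'
#' @param path Manifest file (`.csv` or `.yaml`/`.yml`).
#' @param check_files If `TRUE` (default), error when a referenced trial file
#'   does not exist; paths are resolved relative to the manifest's directory.
#' @return A data frame of class `study_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML manifests")
    entries <- yaml::read_yaml(path)
    m <- do.call(rbind, lapply(entries, function(e)
      data.frame(file = e$file, subject_id = e$subject_id, device = e$device,
                 condition = e$condition, attempt = e$attempt,
                 failed = isTRUE(e$failed),
                 failure_reason = e$failure_reason %||% NA_character_,
                 stringsAsFactors = FALSE)))
  } else {
    m <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!"failure_reason" %in% names(m)) m$failure_reason <- NA_character_
  m$failed <- as.logical(m$failed)
  m <- validate_manifest(m)
  if (check_files) {
    full <- file.path(dirname(path), m$file)
    missing <- !file.exists(full)
    if (any(missing))
      stop("manifest references missing files, e.g.: ", full[which(missing)[1]])
    m$file <- full
  }
  m
}

#' Validate a study manifest data frame
#'
#' Checks the required columns, value ranges, and that
#' (subject, device, condition, attempt) keys are unique.
#'
#' @param m Data frame of manifest entries.
#' @return `m`, classed `study_manifest`, invisibly validated.
#' @export
validate_manifest <- function(m) {
  need <- c("file", "subject_id", "device", "condition", "attempt", "failed")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (!all(m$device %in% c("head", "waist")))
    stop("manifest device must be 'head' or 'waist'")
  if (!all(m$condition %in% 1:6)) stop("manifest condition must be in 1..6")
  if (!all(m$attempt %in% 1:2)) stop("manifest attempt must be in 1..2")
  key <- paste(m$subject_id, m$device, m$condition, m$attempt, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, device, condition, attempt) manifest entries")
  if (!"failure_reason" %in% names(m)) m$failure_reason <- NA_character_
  class(m) <- unique(c("study_manifest", class(m)))
  m
}

#' Write a study manifest as CSV
#' @param m A validated manifest data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(m, path) {
  m <- validate_manifest(m)
  utils::write.csv(as.data.frame(m)[, c("file", "subject_id", "device",
                                        "condition", "attempt", "failed",
                                        "failure_reason")],
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
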