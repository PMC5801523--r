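# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and the signal package): filter design from the
# analog Butterworth prototype via the bilinear transform, applied with an
# explicit difference-equation loop.

# polynomial coefficients (descending powers start) from roots
poly_from_roots <- function(roots) {
  coefs <- 1
  for (r in roots) coefs <- c(coefs, 0) - c(0, r * coefs)
  coefs
}

# digital Butterworth low-pass (order n, cutoff fc, rate fs): analog
# prototype poles, prewarped cutoff, bilinear transform, unity DC gain
oracle_butter <- function(n, fc, fs) {
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  wc <- 2 * fs * tan(pi * fc / fs)
  p <- wc * p_proto
  zp <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))
  b <- b * sum(a) / sum(b)
  list(b = b, a = a)
}

# causal IIR filtering by the raw difference equation (zero initial state)
oracle_filter <- function(ba, x) {
  b <- ba$b / ba$a[1]; a <- ba$a / ba$a[1]
  nb <- length(b); na <- length(a)
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    acc <- 0
    for (j in seq_len(nb)) if (i - j + 1 >= 1) acc <- acc + b[j] * x[i - j + 1]
    if (na > 1) for (j in 2:na) if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
    y[i] <- acc
  }
  y
}

# analytic magnitude of the bilinear-designed Butterworth low-pass
oracle_butter_gain <- function(f, fc, fs, n) {
  1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^(2 * n))
}

# NPL by explicit element-by-element summation
oracle_npl <- function(x, duration_s) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s / duration_s
}

# ICC(2,1) from an aov() two-way decomposition (independent of the
# package's sums-of-squares code)
oracle_icc21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  meas = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + meas, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Spearman by hand: midranks via counting, then the explicit Pearson formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) vapply(v, function(vi)
    sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# build a simple uniform-grid trial recording
make_trial <- function(acc, fs = 50, subject = "S01", device = "waist",
                       condition = 1, attempt = 1, ...) {
  acc <- as.matrix(acc)
  ts <- (seq_len(nrow(acc)) - 1) * (1000 / fs)
  trial_recording(subject, device, condition, attempt, ts, acc,
                  sample_rate_hz = fs, ...)
}

# constant-gravity 3-axis matrix with optional per-axis signals
make_acc <- function(n, x = 0, y = 1000, z = 0) {
  cbind(x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n))
}
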