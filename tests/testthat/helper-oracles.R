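# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition with plain loops, so they share
# no code with the package implementations they check.

oracle_nrmse <- function(x, y) {
  n <- length(x)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + (x[i] - y[i])^2
  100 * sqrt(acc / n) / (max(x) - min(x))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  100 * sxy / sqrt(sxx * syy)
}

oracle_peak <- function(x) {
  best <- 1
  for (i in seq_along(x)) if (x[i] > x[best]) best <- i
  list(time_pct = best - 1, amplitude = x[best])
}

oracle_delta_tp <- function(x, y) oracle_peak(x)$time_pct - oracle_peak(y)$time_pct

oracle_delta_ep <- function(x, y) {
  px <- oracle_peak(x)$amplitude; py <- oracle_peak(y)$amplitude
  100 * abs(px - py) / px
}

# sliding median with reflected edges, computed window by window
oracle_median_filter <- function(x, kernel) {
  p <- (kernel - 1) / 2
  n <- length(x)
  padded <- c(x[p:1], x, x[n:(n - p + 1)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- sort(padded[i:(i + kernel - 1)])
    out[i] <- w[p + 1]
  }
  out
}

# one-sided power spectrum straight from the DFT definition (O(N^2))
oracle_power_spectrum <- function(x, fs) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  power <- vapply(ks, function(k) {
    s <- sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
    Mod(s)^2 / n
  }, numeric(1))
  list(frequencies = ks * fs / n, power = power)
}

# squared magnitude response of an analog Butterworth band-pass of prototype
# order n (applied twice for a forward-backward pass)
butter_bandpass_gain <- function(f, low, high, order, passes = 2) {
  w <- (f^2 - low * high) / (f * (high - low))
  (1 / (1 + w^(2 * order)))^(passes / 2)
}

# gait phase (% cycle) of each time point given heel strikes, clamped to the
# strike span; independent re-derivation for round-trip tests
grid_phase_for_test <- function(tt, strikes) {
  k <- findInterval(tt, strikes)
  k[k < 1] <- 1
  k[k > length(strikes) - 1] <- length(strikes) - 1
  100 * (tt - strikes[k]) / (strikes[k + 1] - strikes[k])
}

random_envelope <- function(n = 101) {
  # smooth positive random curve
  x <- stats::filter(stats::rnorm(n + 20), rep(1 / 7, 7), circular = TRUE)
  x <- as.numeric(x)[1:n]
  x - min(x) + 0.05
}
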