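#' One-sided power spectrum of a signal
#'
#' Diagnostic utility used to inspect where the myoelectric power lies before
#' choosing the band-pass corner frequencies (the 20--400 Hz band shipped as
#' the default was fixed once from such an inspection; it is not re-derived
#' per run).
#'
#' @param signal A `raw_signal` with at least 8 samples.
#' @return A list of class `power_spectrum` with `frequencies` (Hz, from 0 to
#'   the Nyquist frequency, resolution `fs / N`) and `power` (magnitude
#'   squared of the DFT, `|X_k|^2 / N`, non-negative).
#' @export
compute_power_spectrum <- function(signal) {
  signal <- as_raw_signal(signal)
  x <- signal$samples
  n <- length(x)
  if (n < 8L) stop("compute_power_spectrum: signal too short (need >= 8 samples, got ", n, ")")
  X <- stats::fft(x)
  k <- 0:(n %/% 2)
  structure(
    list(frequencies = k * signal$fs / n,
         power = (Mod(X[k + 1])^2) / n),
    class = "power_spectrum"
  )
}

# IIR filtering initialized at the steady state for the signal's first value
# (previous inputs = x0, previous outputs = x0 * DC gain), so constants pass
# without start-up transients
lfilter_ss <- function(b, a, x, x0) {
  g0 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x0, length(b) - 1),
                            init.y = rep(x0 * g0, length(a) - 1)))
}

# forward-backward (zero-phase) application of a digital filter, with
# odd-reflection end padding to keep edge transients out of the signal
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  p <- min(3L * (max(length(bf$b), length(bf$a)) - 1L), n - 1L)
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- lfilter_ss(bf$b, bf$a, ext, ext[1])
  y <- rev(lfilter_ss(bf$b, bf$a, rev(y), y[length(y)]))
  y[(p + 1):(p + n)]
}

check_nyquist <- function(f, fs, what) {
  if (f >= fs / 2) {
    stop(what, " (", f, " Hz) must be below the Nyquist frequency ", fs / 2,
         " Hz; this signal needs fs > ", 2 * f, " Hz")
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass filter forward and backward, so the output
#' is zero-phase: envelope timing is not shifted by filter delay. Ends are
#' odd-reflection padded and each pass starts from the steady state of the
#' boundary value, keeping start-up transients out of the recording. `order`
#' is the order of the low-pass prototype
#' handed to [signal::butter()]; the band-pass transform doubles it, and the
#' forward-backward pass squares the magnitude response.
#'
#' @param signal A `raw_signal`.
#' @param low_hz,high_hz Band corners in Hz; defaults 20 and 400, the band
#'   in which surface-EMG power is concentrated.
#' @param order Butterworth prototype order (default 4).
#' @return A `raw_signal` of equal length with the out-of-band components
#'   (including any DC offset) removed.
#' @export
bandpass_filter <- function(signal, low_hz = 20, high_hz = 400, order = 4) {
  signal <- as_raw_signal(signal)
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("bandpass_filter: need 0 < low_hz < high_hz")
  }
  check_nyquist(high_hz, signal$fs, "bandpass_filter: upper corner")
  bf <- signal::butter(order, c(low_hz, high_hz) / (signal$fs / 2), type = "pass")
  y <- zero_phase_filter(bf, signal$samples)
  raw_signal(y, fs = signal$fs, label = signal$label, t0 = signal$t0)
}

#' Full-wave rectification
#'
#' @param signal A `raw_signal`.
#' @return The element-wise absolute value, same sampling.
#' @export
rectify <- function(signal) {
  signal <- as_raw_signal(signal)
  raw_signal(abs(signal$samples), fs = signal$fs, label = signal$label, t0 = signal$t0)
}

#' Low-pass linear envelope of a rectified signal
#'
#' Zero-phase Butterworth low-pass; 8 Hz is the customary envelope cutoff for
#' gait EMG. Small negative ringing is clipped at zero, since an activation
#' envelope is physically non-negative.
#'
#' @param signal A rectified `raw_signal`.
#' @param cutoff_hz Low-pass cutoff in Hz (default 8).
#' @param order Butterworth order (default 4).
#' @return A `raw_signal` holding the non-negative envelope.
#' @export
lowpass_envelope <- function(signal, cutoff_hz = 8, order = 4) {
  signal <- as_raw_signal(signal)
  if (cutoff_hz <= 0) stop("lowpass_envelope: cutoff must be positive")
  check_nyquist(cutoff_hz, signal$fs, "lowpass_envelope: cutoff")
  bf <- signal::butter(order, cutoff_hz / (signal$fs / 2), type = "low")
  y <- zero_phase_filter(bf, signal$samples)
  raw_signal(pmax(y, 0), fs = signal$fs, label = signal$label, t0 = signal$t0)
}

#' Sliding-window median filter
#'
#' Nonlinear smoother used on the 101-point gait-cycle arrays to remove
#' residual impulsive noise. Edges are handled by reflecting the first and
#' last `(kernel - 1) / 2` samples.
#'
#' @param x Numeric vector.
#' @param kernel Odd window length, `1 <= kernel <= length(x)` (default 5).
#' @return Filtered vector of the same length.
#' @export
median_filter <- function(x, kernel = 5) {
  x <- as.numeric(x)
  if (kernel %% 2 != 1 || kernel < 1) stop("median_filter: kernel must be a positive odd integer")
  if (kernel > length(x)) stop("median_filter: kernel exceeds signal length")
  if (kernel == 1L) return(x)
  p <- (kernel - 1L) / 2L
  n <- length(x)
  # interior via the fast running-median; edge windows recomputed on the
  # reflection-padded signal
  y <- as.numeric(stats::runmed(x, kernel, endrule = "keep"))
  xp <- c(rev(x[seq_len(p)]), x, rev(x[(n - p + 1L):n]))
  for (i in c(seq_len(p), (n - p + 1L):n)) {
    y[i] <- stats::median(xp[i:(i + kernel - 1L)])
  }
  y
}

#' Min-max normalization parameters
#'
#' @param y_min,y_max Observed minimum and maximum of the original signal.
#' @return List of class `norm_params` with `y_min`, `y_max` and a
#'   `degenerate` flag (`TRUE` when `y_max == y_min`).
#' @export
norm_params <- function(y_min, y_max) {
  if (y_max < y_min) stop("norm_params: y_max < y_min")
  structure(list(y_min = y_min, y_max = y_max, degenerate = y_max == y_min),
            class = "norm_params")
}

#' Min-max normalization to [0, 1]
#'
#' Rescales `y` to `(y - min) / (max - min)`, storing the parameters so the
#' map can be inverted exactly. A constant input cannot be rescaled; it is
#' returned as all zeros with the parameters flagged degenerate, and such
#' cycles are excluded from correlation-based evaluation downstream.
#'
#' @param x Numeric vector, length >= 2.
#' @return List with `values` (in `[0, 1]`) and `params` (a [norm_params()]).
#' @export
minmax_normalize <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("minmax_normalize: need at least 2 values")
  if (anyNA(x) || !all(is.finite(x))) stop("minmax_normalize: non-finite input")
  lo <- min(x); hi <- max(x)
  p <- norm_params(lo, hi)
  values <- if (p$degenerate) rep(0, length(x)) else (x - lo) / (hi - lo)
  list(values = values, params = p)
}

#' Invert min-max normalization
#'
#' Computes `y = y_norm * (y_max - y_min) + y_min`. Inputs need not lie in
#' `[0, 1]`: model predictions may overshoot slightly and are mapped through
#' the same affine inverse. Degenerate parameters reproduce the constant.
#'
#' @param x Numeric vector of normalized values.
#' @param params A [norm_params()] stored at normalization time.
#' @return Numeric vector on the original scale.
#' @export
denormalize <- function(x, params) {
  stopifnot(inherits(params, "norm_params"))
  if (params$degenerate) return(rep(params$y_min, length(x)))
  as.numeric(x) * (params$y_max - params$y_min) + params$y_min
}

#' EMG conditioning chain: band-pass, rectify, envelope
#'
#' Runs the per-trial part of the EMG processing chain on a raw recording:
#' zero-phase Butterworth band-pass (default 20--400 Hz), full-wave
#' rectification, then a zero-phase low-pass (default 8 Hz) linear envelope.
#' Stride segmentation, 101-point time normalization, median filtering and
#' per-stride min-max normalization are applied downstream by
#' [normalize_cycles()].
#'
#' @param raw A `raw_signal` with the raw EMG.
#' @param low_hz,high_hz Band-pass corners (Hz).
#' @param envelope_hz Envelope low-pass cutoff (Hz).
#' @param order Butterworth prototype order for both filters.
#' @return A `raw_signal` holding the continuous activation envelope.
#' @export
process_emg <- function(raw, low_hz = 20, high_hz = 400, envelope_hz = 8, order = 4) {
  raw |>
    bandpass_filter(low_hz = low_hz, high_hz = high_hz, order = order) |>
    rectify() |>
    lowpass_envelope(cutoff_hz = envelope_hz, order = order)
}

#' IMU conditioning chain
#'
#' IMU channels skip the EMG-specific filtering: they are segmented at heel
#' strikes, time-normalized to 101 points, median-filtered and min-max
#' normalized per stride. This is a thin named wrapper over
#' [normalize_cycles()] kept for symmetry with [process_emg()].
#'
#' @param raw A `raw_signal` with one IMU axis.
#' @param heel_strikes Ascending heel-strike times (s).
#' @param ... Passed to [normalize_cycles()].
#' @return List of `normalized_cycle` objects, one per stride.
#' @export
process_imu <- function(raw, heel_strikes, ...) {
  normalize_cycles(raw, heel_strikes, ...)
}
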