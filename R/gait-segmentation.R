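#' One stride of a continuous signal
#'
#' @param samples Samples falling inside the stride.
#' @param fs Sampling rate (Hz).
#' @param start_s,end_s Stride boundaries (consecutive heel strikes, s).
#' @param rel_times Sample times relative to `start_s`; defaults to a regular
#'   grid starting at 0 that treats `samples` as spanning the whole closed
#'   stride interval (convenient when constructing segments directly from a
#'   vector).
#' @param channel Source channel name.
#' @return Object of class `stride_segment`.
#' @export
stride_segment <- function(samples, fs, start_s = 0,
                           end_s = start_s + (length(samples) - 1) / fs,
                           rel_times = NULL, channel = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) stop("stride_segment: need at least 2 samples")
  if (end_s <= start_s) stop("stride_segment: end_s must exceed start_s")
  if (is.null(rel_times)) {
    rel_times <- seq(0, end_s - start_s, length.out = length(samples))
  }
  if (length(rel_times) != length(samples)) {
    stop("stride_segment: rel_times/samples length mismatch")
  }
  structure(list(samples = samples, fs = fs, start_s = start_s, end_s = end_s,
                 rel_times = as.numeric(rel_times), channel = channel),
            class = "stride_segment")
}

#' Split a continuous signal into strides at heel strikes
#'
#' Each consecutive pair of heel strikes defines one stride covering the
#' half-open interval `[strike_k, strike_{k+1})`, so the 0% point of a stride
#' is never duplicated with the 100% point of its predecessor. Data before
#' the first and after the last strike are discarded; strike pairs falling
#' outside the recording span are dropped with a warning.
#'
#' @param signal A `raw_signal`.
#' @param heel_strikes Strictly ascending heel-strike times in seconds.
#' @return List of `stride_segment` objects (possibly empty).
#' @export
segment_strides <- function(signal, heel_strikes) {
  signal <- as_raw_signal(signal)
  hs <- as.numeric(heel_strikes)
  if (anyNA(hs) || is.unsorted(hs, strictly = TRUE)) {
    stop("segment_strides: heel strikes must be strictly ascending")
  }
  if (length(hs) < 2L) {
    warning("segment_strides: fewer than 2 heel strikes; no strides extracted")
    return(list())
  }
  tt <- signal_times(signal)
  t_lo <- tt[1]; t_hi <- tt[length(tt)]
  segs <- list()
  dropped <- 0L
  for (k in seq_len(length(hs) - 1L)) {
    s0 <- hs[k]; s1 <- hs[k + 1L]
    idx <- which(tt >= s0 & tt < s1)
    if (s0 < t_lo || s1 > t_hi + 1 / signal$fs || length(idx) < 2L) {
      dropped <- dropped + 1L
      next
    }
    segs[[length(segs) + 1L]] <- stride_segment(
      samples = signal$samples[idx], fs = signal$fs,
      start_s = s0, end_s = s1,
      rel_times = tt[idx] - s0, channel = signal$label
    )
  }
  if (dropped > 0L) {
    warning("segment_strides: dropped ", dropped,
            " stride(s) falling outside the recording span")
  }
  segs
}

#' Time-normalize a stride onto the 0--100% gait-cycle grid
#'
#' Resamples one stride onto `n` equally spaced phase points by linear
#' interpolation of the samples at their true relative times (linear
#' interpolation is monotone, never overshoots, and preserves the
#' non-negativity of envelopes). Phase points beyond the last available
#' sample (the stride interval is half-open) take the nearest sample value.
#'
#' @param segment A `stride_segment`.
#' @param n Number of phase points (default 101, i.e. 0, 1, ..., 100% of the
#'   gait cycle).
#' @param method `"linear"` (default; monotone, no overshoot, preserves
#'   envelope non-negativity) or `"spline"` (natural cubic).
#' @return Numeric vector of length `n`.
#' @export
time_normalize <- function(segment, n = 101, method = c("linear", "spline")) {
  stopifnot(inherits(segment, "stride_segment"))
  method <- match.arg(method)
  if (length(segment$samples) < 2L) stop("time_normalize: segment too short")
  dur <- segment$end_s - segment$start_s
  xout <- seq(0, dur, length.out = n)
  if (method == "spline") {
    return(stats::spline(segment$rel_times, segment$samples, xout = xout,
                         method = "natural")$y)
  }
  stats::approx(segment$rel_times, segment$samples, xout = xout,
                method = "linear", rule = 2)$y
}

#' A stride expressed on the normalized gait-cycle grid
#'
#' @param values Exactly `n_points` values (index i = i% of the gait cycle).
#' @param params [norm_params()] that map the values back to the original
#'   amplitude scale; `NULL` for cycles that were never min-max normalized.
#' @param start_s,end_s Stride boundary times (s).
#' @param channel Source channel name.
#' @param n_points Grid length (101 everywhere in this package).
#' @return Object of class `normalized_cycle`.
#' @export
normalized_cycle <- function(values, params = NULL, start_s = NA_real_,
                             end_s = NA_real_, channel = "signal",
                             n_points = 101L) {
  values <- as.numeric(values)
  if (length(values) != n_points) {
    stop("normalized_cycle: expected exactly ", n_points, " values, got ", length(values))
  }
  if (!is.null(params)) stopifnot(inherits(params, "norm_params"))
  structure(list(values = values, params = params, start_s = start_s,
                 end_s = end_s, channel = channel),
            class = "normalized_cycle")
}

#' Segment, time-normalize, median-filter and min-max normalize
#'
#' The shared per-stride tail of the processing chain: split the signal at
#' heel strikes, resample each stride to 101 phase points, apply the median
#' filter, then min-max normalize (in that order, so the output still attains
#' exactly 0 and 1), keeping the normalization parameters for exact
#' inversion.
#'
#' @param signal A `raw_signal` (an EMG envelope or an IMU axis).
#' @param heel_strikes Ascending heel-strike times (s).
#' @param n_points Phase grid length (default 101).
#' @param median_kernel Odd median-filter window (default 5); use 1 to skip.
#' @param normalize Apply per-stride min-max normalization (default TRUE).
#' @return List of `normalized_cycle` objects, one per stride.
#' @export
normalize_cycles <- function(signal, heel_strikes, n_points = 101,
                             median_kernel = 5, normalize = TRUE) {
  segs <- segment_strides(signal, heel_strikes)
  lapply(segs, function(sg) {
    v <- time_normalize(sg, n = n_points)
    v <- median_filter(v, kernel = median_kernel)
    if (normalize) {
      nm <- minmax_normalize(v)
      normalized_cycle(nm$values, nm$params, sg$start_s, sg$end_s,
                       channel = sg$channel, n_points = n_points)
    } else {
      normalized_cycle(v, NULL, sg$start_s, sg$end_s,
                       channel = sg$channel, n_points = n_points)
    }
  })
}

#' Reconstruct a continuous signal from per-stride normalized cycles
#'
#' Inverts the segmentation: each cycle is denormalized with its own stored
#' min-max parameters and resampled from the 101-point phase grid onto that
#' stride's time grid; strides are concatenated contiguously. The 100% point
#' of each cycle coincides with the next cycle's 0% point and is emitted only
#' once (it is kept for the final cycle).
#'
#' @param cycles List of `normalized_cycle` objects, one per consecutive
#'   heel-strike pair. Cycles without stored parameters are treated as
#'   already being on the output scale.
#' @param heel_strikes Ascending heel-strike times; `length(cycles) + 1`.
#' @param fs_out Output sampling rate in Hz.
#' @return A `raw_signal` spanning `[first strike, last strike]`.
#' @export
reconstruct_time_domain <- function(cycles, heel_strikes, fs_out) {
  hs <- as.numeric(heel_strikes)
  if (length(cycles) != length(hs) - 1L) {
    stop("reconstruct_time_domain: ", length(cycles), " cycle(s) but ",
         length(hs), " heel strikes (need one cycle per consecutive pair)")
  }
  if (is.unsorted(hs, strictly = TRUE)) stop("heel strikes must be ascending")
  tt <- seq(hs[1], hs[length(hs)], by = 1 / fs_out)
  k <- findInterval(tt, hs, rightmost.closed = TRUE)
  k[k > length(cycles)] <- length(cycles)
  out <- numeric(length(tt))
  for (j in seq_along(cycles)) {
    cyc <- cycles[[j]]
    stopifnot(inherits(cyc, "normalized_cycle"))
    vals <- if (is.null(cyc$params)) cyc$values else denormalize(cyc$values, cyc$params)
    sel <- which(k == j)
    if (!length(sel)) next
    phase <- (tt[sel] - hs[j]) / (hs[j + 1] - hs[j])
    grid <- seq(0, 1, length.out = length(vals))
    out[sel] <- stats::approx(grid, vals, xout = phase, rule = 2)$y
  }
  raw_signal(out, fs = fs_out, label = cycles[[1]]$channel, t0 = hs[1])
}
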