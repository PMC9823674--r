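test_that("power spectrum localizes tones and matches the DFT definition", {
  fs <- 1000
  tt <- (0:499) / fs
  ps <- compute_power_spectrum(raw_signal(sin(2 * pi * 50 * tt), fs))
  expect_equal(ps$frequencies[which.max(ps$power)], 50)

  ps0 <- compute_power_spectrum(raw_signal(rep(3, 64), fs))
  expect_equal(which.max(ps0$power), 1L)  # all power at DC
  expect_lt(sum(ps0$power[-1]), 1e-18 * ps0$power[1])

  # two tones on exact bins, against the O(N^2) DFT oracle
  tt <- (0:99) / fs
  x <- sin(2 * pi * 30 * tt) + 0.5 * sin(2 * pi * 200 * tt)
  ps <- compute_power_spectrum(raw_signal(x, fs))
  orc <- oracle_power_spectrum(x, fs)
  expect_equal(ps$frequencies, orc$frequencies)
  expect_equal(ps$power, orc$power, tolerance = 1e-10)
  top2 <- ps$frequencies[order(ps$power, decreasing = TRUE)[1:2]]
  expect_setequal(top2, c(30, 200))

  expect_error(compute_power_spectrum(raw_signal(c(1, 2, 3), fs)), "too short")
})

test_that("band-pass filter passes the band, rejects DC and low frequencies", {
  fs <- 2000
  tt <- (0:(4 * fs - 1)) / fs
  mid <- (fs + 1):(3 * fs)  # interior, away from filtfilt edge transients

  y <- bandpass_filter(raw_signal(sin(2 * pi * 100 * tt), fs))
  expect_lt(abs(max(abs(y$samples[mid])) - 1), 0.05)

  # 90 Hz passband gain within 5% of unity (and of the analytic response)
  y90 <- bandpass_filter(raw_signal(sin(2 * pi * 90 * tt), fs))
  g90 <- sqrt(mean(y90$samples[mid]^2)) / sqrt(0.5)
  expect_lt(abs(g90 - 1), 0.05)
  expect_lt(abs(butter_bandpass_gain(90, 20, 400, 4) - 1), 0.01)

  # 2 Hz: >= 20 dB attenuation, consistent with the analytic magnitude
  y2 <- bandpass_filter(raw_signal(sin(2 * pi * 2 * tt), fs))
  att_db <- -20 * log10(sqrt(mean(y2$samples[mid]^2)) / sqrt(0.5))
  expect_gt(att_db, 20)
  expect_gt(-20 * log10(butter_bandpass_gain(2, 20, 400, 4)), 20)

  # near-Nyquist attenuation
  yh <- bandpass_filter(raw_signal(sin(2 * pi * 0.45 * fs * tt), fs))
  expect_gt(-20 * log10(sqrt(mean(yh$samples[mid]^2)) / sqrt(0.5)), 20)

  # DC rejection
  yc <- bandpass_filter(raw_signal(rep(3, 2000), fs))
  expect_lt(abs(mean(yc$samples)), 1e-6 * 3)

  expect_error(bandpass_filter(raw_signal(rnorm(100), 500), 20, 400),
               "fs > 800")
  expect_error(bandpass_filter(raw_signal(rnorm(100), 2000), 400, 20))
})

test_that("rectification is the elementwise absolute value", {
  expect_equal(rectify(raw_signal(c(-1, 2, -3), 100))$samples, c(1, 2, 3))
  x <- abs(rnorm(50)) + 0.1
  expect_equal(rectify(raw_signal(x, 100))$samples, x)
  expect_equal(rectify(raw_signal(numeric(9), 100))$samples, numeric(9))
})

test_that("low-pass envelope recovers the mean of a rectified sine", {
  fs <- 2000
  tt <- (0:(4 * fs - 1)) / fs
  rect <- rectify(raw_signal(sin(2 * pi * 100 * tt), fs))
  env <- lowpass_envelope(rect)
  mid <- env$samples[(fs + 1):(3 * fs)]
  expect_lt(abs(mean(mid) - 2 / pi), 0.1 * 2 / pi)
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.1)  # ripple < 10%

  expect_equal(lowpass_envelope(raw_signal(rep(0.5, 1000), fs))$samples,
               rep(0.5, 1000), tolerance = 1e-6)
  expect_equal(lowpass_envelope(raw_signal(numeric(1000), fs))$samples,
               numeric(1000))
  expect_true(all(lowpass_envelope(rect)$samples >= 0))
  expect_error(lowpass_envelope(raw_signal(rnorm(100), 10), cutoff_hz = 8),
               "Nyquist")
})

test_that("median filter removes impulses and matches the per-window oracle", {
  expect_equal(median_filter(c(0, 0, 9, 0, 0), 3), rep(0, 5))
  ramp <- 1:20
  expect_equal(median_filter(ramp, 3)[2:19], ramp[2:19])
  expect_error(median_filter(1:10, 4), "odd")
  expect_error(median_filter(1:3, 5), "exceeds")

  set.seed(101)
  for (i in 1:1000) {
    n <- sample(7:40, 1)
    k <- sample(c(3, 5, 7), 1)
    x <- rnorm(n)
    expect_identical(median_filter(x, k), oracle_median_filter(x, k))
  }
})

test_that("min-max normalization maps to [0,1] and inverts exactly", {
  nm <- minmax_normalize(c(2, 4, 6))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(nm$params$y_min, 2)
  expect_equal(nm$params$y_max, 6)
  expect_false(nm$params$degenerate)
  expect_equal(denormalize(c(0, 0.5, 1), nm$params), c(2, 4, 6))

  x01 <- c(0, 0.2, 1, 0.6)
  nm2 <- minmax_normalize(x01)
  expect_equal(nm2$values, x01)
  expect_identical(denormalize(x01, norm_params(0, 1)), x01)

  nmc <- minmax_normalize(c(5, 5, 5))
  expect_equal(nmc$values, c(0, 0, 0))
  expect_true(nmc$params$degenerate)
  expect_equal(denormalize(c(0.3, 0.9), nmc$params), c(5, 5))

  set.seed(7)
  for (i in 1:200) {
    x <- rnorm(sample(2:50, 1), sd = 10^runif(1, -3, 3))
    nm <- minmax_normalize(x)
    expect_true(all(nm$values >= 0 & nm$values <= 1))
    if (!nm$params$degenerate) {
      expect_equal(min(nm$values), 0)
      expect_equal(max(nm$values), 1)
      expect_equal(denormalize(nm$values, nm$params), x, tolerance = 1e-12)
    }
  }
})

test_that("IMU channels go through segmentation and min-max only", {
  fs <- 200
  tt <- (0:(10 * fs - 1)) / fs
  sig <- raw_signal(sin(2 * pi * tt) + 0.2 * sin(2 * pi * 3 * tt), fs, "thigh_gyro_x")
  cycles <- process_imu(sig, heel_strikes = 1:8)
  expect_length(cycles, 7)
  for (cyc in cycles[c(1, 7)]) {
    expect_length(cyc$values, 101)
    expect_true(all(cyc$values >= 0 & cyc$values <= 1))
    expect_equal(min(cyc$values), 0)
    expect_equal(max(cyc$values), 1)
    expect_false(cyc$params$degenerate)
  }
})

test_that("cubic time normalization is available and exact on smooth input", {
  phase <- seq(0, 1, length.out = 37)
  seg <- stride_segment(sin(2 * pi * phase), fs = 36)
  out <- time_normalize(seg, method = "spline")
  truth <- sin(2 * pi * seq(0, 1, length.out = 101))
  # cubic error well below the linear-interpolation bound on the interior
  expect_lt(max(abs(out - truth)[10:90]), 5e-4)
})

test_that("EMG chain recovers burst timing and is scale-invariant after min-max", {
  fs <- 1000
  tt <- (0:(5 * fs - 1)) / fs
  centers <- c(1.0, 2.2, 3.6)
  env <- rowSums(vapply(centers, function(c0) exp(-(tt - c0)^2 / (2 * 0.05^2)),
                        numeric(length(tt))))
  set.seed(11)
  x <- env * sin(2 * pi * 150 * tt) + rnorm(length(tt), 0, 0.01)
  out <- process_emg(raw_signal(x, fs))
  for (c0 in centers) {
    win <- which(abs(tt - c0) < 0.25)
    t_peak <- tt[win[which.max(out$samples[win])]]
    expect_lt(abs(t_peak - c0), 0.010)  # within 10 ms
  }

  expect_equal(process_emg(raw_signal(numeric(2000), fs))$samples, numeric(2000))

  # pre-normalization scale equivariance, post-normalization invariance
  x2 <- process_emg(raw_signal(2 * x, fs))
  expect_equal(x2$samples, 2 * out$samples, tolerance = 1e-9)
  expect_equal(minmax_normalize(x2$samples)$values,
               minmax_normalize(out$samples)$values, tolerance = 1e-9)
})
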