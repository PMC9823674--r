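test_that("activation profiles place bursts where specified, circularly", {
  sp <- muscle_spec("m", list(list(center = 40, width = 5, amp = 1)))
  prof <- activation_profile(sp, 0:100)
  expect_equal(which.max(prof) - 1, 40)

  # burst near 100% wraps into early phase
  spw <- muscle_spec("m", list(list(center = 98, width = 4, amp = 1)))
  profw <- activation_profile(spw, 0:100, baseline = 0)
  expect_gt(min(profw[1:3]), 0.5)  # mass at 0-2%

  # hamstring stance burst is larger in slow than fast walking
  ham <- default_muscle_specs()$biceps_femoris
  slow <- activation_profile(ham, 25:35, speed = "slow")
  fast <- activation_profile(ham, 25:35, speed = "fast")
  expect_gt(max(slow), max(fast))

  expect_error(muscle_spec("m", list(list(center = 120, width = 5, amp = 1))))
  expect_error(muscle_spec("m", list(list(center = 10, width = -1, amp = 1))))
})

test_that("envelope resampling to 101 points preserves the peak location", {
  set.seed(21)
  for (i in 1:30) {
    sp <- muscle_spec("m", list(list(center = runif(1, 0, 100),
                                     width = runif(1, 4, 12), amp = 1)))
    fine <- activation_profile(sp, seq(0, 100, length.out = 1001))
    coarse <- activation_profile(sp, seq(0, 100, length.out = 101))
    expect_lt(abs((which.max(fine) - 1) / 10 - (which.max(coarse) - 1)), 1 + 1e-9)
    expect_true(all(coarse >= 0))
    expect_gt(max(coarse), 0)
  }
})

test_that("IMU synthesis is deterministic, periodic, and decouplable", {
  subj <- subject_config("S01", seed = 3)
  phase <- rep(seq(0, 99.5, by = 0.5), 2)  # two identical strides
  act <- matrix(abs(sin(outer(phase / 100 * 2 * pi, 1:9))), length(phase), 9)
  dact <- matrix(0, length(phase), 9)
  mixing <- list(Wa = matrix(1, 24, 9), Wd = matrix(0, 24, 9))

  a <- imu_from_activations(subj, phase, act, dact, mixing, noise_sd = 0)
  b <- imu_from_activations(subj, phase, act, dact, mixing, noise_sd = 0)
  expect_identical(a, b)

  # zero noise: stride-periodic inputs give stride-periodic channels
  n <- length(phase) / 2
  expect_equal(a[1:n, ], a[(n + 1):(2 * n), ], tolerance = 1e-12)

  # coupling zeroed: channels ignore the activations entirely
  act2 <- act * 5 + 1
  c1 <- imu_from_activations(subj, phase, act, dact, mixing, coupling = 0, noise_sd = 0)
  c2 <- imu_from_activations(subj, phase, act2, dact, mixing, coupling = 0, noise_sd = 0)
  expect_identical(c1, c2)
})

test_that("raw-EMG synthesis is recoverable by the conditioning chain", {
  set.seed(8)
  fs <- 1000
  tt <- seq(0, 4, by = 1 / fs)
  d <- (100 * tt / 1.0 - 45 + 50) %% 100 - 50   # bump at 45% of 1 s cycles
  env <- 0.1 + exp(-d^2 / (2 * 8^2))
  raw <- synthesize_raw_emg(env, fs = fs)
  rec <- process_emg(raw)
  expect_gt(pearson_r(env[500:3500], rec$samples[500:3500]), 95)

  # zero envelope: output stays near zero
  raw0 <- synthesize_raw_emg(numeric(2001), fs = fs)
  rec0 <- process_emg(raw0)
  expect_lt(max(rec0$samples), 1e-6)

  # sub-band drift alone is removed by the band-pass stage
  drift <- raw_signal(0.8 * sin(2 * pi * 0.3 * tt), fs)
  recd <- process_emg(drift)
  expect_lt(max(recd$samples[500:3500]), 0.02)
})

test_that("study generation is deterministic and correctly counted", {
  study <- generate_study(n_subjects = 3, trials_per_subject = 2,
                          strides_per_trial = 10, seed = 4)
  expect_length(study$trials, 6)
  for (tr in study$trials) {
    expect_length(tr$events, 11)  # strikes = strides + 1
    expect_equal(nrow(tr$truth[[1]]), 10)
  }
  total <- sum(vapply(study$trials, function(tr) length(tr$events) - 1L, integer(1)))
  expect_equal(total, 60)

  expect_error(generate_study(strides_per_trial = 0), "strides_per_trial")

  # same seed -> byte-identical files
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(generate_study(2, 1, 5, seed = 99), d1)
  write_study(generate_study(2, 1, 5, seed = 99), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a linear ridge probe reads the targets from noise-free sensors", {
  study <- generate_study(n_subjects = 2, trials_per_subject = 1,
                          strides_per_trial = 15, seed = 12,
                          noise_imu = 0, emg_noise = 0)
  samples <- build_study_samples(study)
  expect_gt(linear_probe_r(samples, "gastrocnemius"), 99)
  expect_gt(linear_probe_r(samples, "semitendinosus"), 99)
})

test_that("written studies round-trip through the file readers", {
  study <- generate_study(n_subjects = 1, trials_per_subject = 1,
                          strides_per_trial = 6, seed = 31)
  dir <- file.path(tempdir(), "study_rt")
  write_study(study, dir)
  back <- read_study(dir)
  tr0 <- study$trials[[1]]; tr1 <- back$trials[[1]]
  expect_equal(tr1$subject_id, tr0$subject_id)
  expect_equal(tr1$speed, tr0$speed)
  expect_equal(tr1$events, tr0$events, tolerance = 1e-9)
  expect_equal(attr(tr1$imu, "fs"), 200, tolerance = 1e-6)
  expect_equal(tr1$imu[["foot_accel_x"]]$samples,
               signif(tr0$imu[["foot_accel_x"]], 10), tolerance = 1e-9)
  # processed samples agree between in-memory and on-disk routes
  s0 <- build_samples(tr0)
  s1 <- build_samples(tr1)
  expect_equal(s1[[3]]$features, s0[[3]]$features, tolerance = 1e-6)
  expect_equal(s1[[3]]$targets$soleus$values, s0[[3]]$targets$soleus$values,
               tolerance = 1e-4)
  unlink(dir, recursive = TRUE)
})

test_that("irregular or incomplete trial files are rejected", {
  dir <- file.path(tempdir(), "badfiles")
  dir.create(dir, showWarnings = FALSE)
  tm <- (0:99) / 100
  tm[50] <- tm[50] + 0.004  # 40% jitter on one interval
  data.table::fwrite(data.frame(time_s = tm, emg_soleus = rnorm(100)),
                     file.path(dir, "bad_emg.csv"))
  expect_error(read_channels(file.path(dir, "bad_emg.csv")), "irregular")

  df <- data.frame(time_s = (0:99) / 100, emg_soleus = rnorm(100))
  df$emg_soleus[10] <- NA
  data.table::fwrite(df, file.path(dir, "na_emg.csv"))
  expect_error(read_channels(file.path(dir, "na_emg.csv")), "missing")

  data.table::fwrite(data.frame(heel_strike_s = c(1, 0.5)), file.path(dir, "ev.csv"))
  expect_error(read_events(file.path(dir, "ev.csv")), "ascending")
  unlink(dir, recursive = TRUE)
})
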