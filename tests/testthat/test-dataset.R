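# lightweight stand-in samples: split/holdout only need ids
fake_samples <- function(n, subjects = c("S01", "S02", "S03")) {
  lapply(seq_len(n), function(i) {
    structure(list(features = NULL, targets = NULL,
                   subject_id = subjects[(i - 1) %% length(subjects) + 1],
                   trial_id = sprintf("T%02d", (i - 1) %/% 30 + 1),
                   stride_index = i, speed = "normal"),
              class = "gait_cycle_sample")
  })
}

sample_key <- function(s) paste(s$subject_id, s$trial_id, s$stride_index)

test_that("samples are assembled per stride with the canonical channel block", {
  study <- generate_study(n_subjects = 1, trials_per_subject = 1,
                          strides_per_trial = 12, seed = 5)
  trial <- study$trials[[1]]
  samples <- build_samples(trial)
  expect_length(samples, 12)
  for (s in samples[c(1, 12)]) {
    expect_equal(dim(s$features), c(101, 24))
    expect_equal(colnames(s$features), imu_channel_order())
    expect_true(all(s$features >= 0 & s$features <= 1))
    expect_length(s$targets, 9)
    expect_true(all(vapply(s$targets, function(t) length(t$values), integer(1)) == 101))
  }

  # shuffled file column order must not change the feature block
  trial2 <- trial
  perm <- c(1, sample(2:25))
  trial2$imu <- trial$imu[, perm]
  samples2 <- build_samples(trial2)
  expect_equal(samples2[[1]]$features, samples[[1]]$features)

  # missing channel is rejected by name
  trial3 <- trial
  trial3$imu <- trial$imu[, setdiff(names(trial$imu), "shank_gyro_z")]
  expect_error(build_samples(trial3), "shank_gyro_z")
  trial4 <- trial
  trial4$emg <- trial$emg[, setdiff(names(trial$emg), "emg_soleus")]
  expect_error(build_samples(trial4, muscles = muscle_names()), "emg_soleus")
})

test_that("implausibly short strides are excluded from the sample set", {
  study <- generate_study(n_subjects = 1, trials_per_subject = 1,
                          strides_per_trial = 10, seed = 5)
  trial <- study$trials[[1]]
  # inject a heel strike 0.15 s after an existing one: creates one implausible
  # stride and leaves its neighbour plausible
  trial$events <- sort(c(trial$events, trial$events[4] + 0.15))
  samples <- build_samples(trial)
  expect_length(samples, 10)  # 11 strides now, 1 excluded
})

test_that("80:15:5 split has the documented rounding and is seed-stable", {
  sp <- split_dataset(fake_samples(100), seed = 3)
  expect_equal(vapply(sp[c("train", "validation", "test")], length, integer(1)),
               c(train = 80, validation = 15, test = 5))

  sp2 <- split_dataset(fake_samples(5440), seed = 3)
  expect_equal(length(sp2$train), 4352)
  expect_equal(length(sp2$validation), 816)
  expect_equal(length(sp2$test), 272)

  # determinism: identical membership under the same seed
  a <- split_dataset(fake_samples(100), seed = 9)
  b <- split_dataset(fake_samples(100), seed = 9)
  for (g in c("train", "validation", "test")) {
    expect_identical(vapply(a[[g]], sample_key, character(1)),
                     vapply(b[[g]], sample_key, character(1)))
  }

  expect_error(split_dataset(fake_samples(100), ratios = c(0.8, 0.3, 0.1)),
               "sum")
  expect_error(split_dataset(fake_samples(10)), "at least 20")
})

test_that("split groups are disjoint and the unseen subject is exclusive", {
  for (n in c(100, 473, 1000)) {
    sp <- split_dataset(fake_samples(n), seed = n, unseen_subject = "S02")
    keys <- lapply(sp[c("train", "validation", "test")],
                   function(g) vapply(g, sample_key, character(1)))
    expect_equal(sum(lengths(keys)) + length(sp$unseen_subject), n)
    expect_equal(anyDuplicated(unlist(keys)), 0)
    subj <- function(g) unique(vapply(g, `[[`, character(1), "subject_id"))
    expect_false("S02" %in% unlist(lapply(sp[c("train", "validation", "test")], subj)))
    expect_equal(subj(sp$unseen_subject), "S02")
  }
})

test_that("trial-level splitting keeps whole trials together", {
  sp <- split_dataset(fake_samples(300), seed = 2, by = "trial")
  for (g in c("train", "validation", "test")) {
    trials <- vapply(sp[[g]], function(s) paste(s$subject_id, s$trial_id), character(1))
    for (tr in unique(trials)) {
      # every stride of this trial is in this group
      expect_equal(sum(trials == tr),
                   sum(vapply(fake_samples(300), function(s)
                     paste(s$subject_id, s$trial_id) == tr, logical(1))) / 1)
    }
  }
  total <- sum(vapply(sp[c("train", "validation", "test")], length, integer(1)))
  expect_equal(total, 300)
})

test_that("subject holdout is total and validated", {
  ss <- fake_samples(60)
  hd <- holdout_subject(ss, "S03")
  expect_equal(length(hd$remaining) + length(hd$unseen), 60)
  expect_true(all(vapply(hd$unseen, `[[`, character(1), "subject_id") == "S03"))
  expect_false("S03" %in% vapply(hd$remaining, `[[`, character(1), "subject_id"))
  expect_error(holdout_subject(ss, "S99"), "not present")

  two <- fake_samples(40, subjects = c("A", "B"))
  hd2 <- holdout_subject(two, "B")
  expect_equal(unique(vapply(hd2$remaining, `[[`, character(1), "subject_id")), "A")
})

test_that("split manifest lists every sample with its group", {
  sp <- split_dataset(fake_samples(60), seed = 4, unseen_subject = "S01")
  mf <- split_manifest(sp)
  expect_equal(nrow(mf), 60)
  expect_setequal(unique(mf$group), c("train", "validation", "test", "unseen_subject"))
})

test_that("feature/target matrices follow the documented layout", {
  study <- generate_study(n_subjects = 1, trials_per_subject = 1,
                          strides_per_trial = 5, seed = 2)
  samples <- build_samples(study$trials[[1]])
  mm <- samples_to_matrices(samples, "soleus")
  expect_equal(dim(mm$X), c(5, 2424))
  expect_equal(dim(mm$A), c(5, 24, 101))
  expect_equal(dim(mm$Y), c(5, 101))
  # flattening is column-major over the 101 x 24 block
  expect_equal(mm$X[2, ], as.vector(samples[[2]]$features))
  expect_equal(mm$X[2, 102:202], unname(samples[[2]]$features[1:101, 2]))
  # sequence layout: A[i, c, t] = features[t, c]
  expect_equal(mm$A[3, 7, 55], unname(samples[[3]]$features[55, 7]))
  expect_error(samples_to_matrices(samples, "deltoid"), "deltoid")

  # multi-output variant: target blocks concatenated muscle by muscle
  mm2 <- samples_to_matrices(samples, c("soleus", "gastrocnemius"))
  expect_equal(dim(mm2$Y), c(5, 202))
  expect_equal(mm2$Y[, 1:101], mm$Y)
  expect_equal(mm2$Y[4, 102:202], samples[[4]]$targets$gastrocnemius$values)
  est <- build_estimator(model_config("fnn", hidden_layers = 1, hidden_units = 8,
                                      max_epochs = 5, early_stop_patience = 0,
                                      dropout_rate = 0),
                         c(101, 24), n_outputs = 202)
  est <- fit_estimator(est, mm2, mm2)
  P <- predict(est, mm2)
  expect_equal(dim(P), c(5, 202))
  expect_true(all(P > 0 & P < 1))
})
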