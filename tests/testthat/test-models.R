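# small, noiseless sequence-regression tasks, one per architecture's
# structure. "pointwise": the target at each phase step is a smooth function
# of the first channel there (weight-shared across steps, suits the
# per-step LSTM readout). "blend": the target mixes two bump shapes by a
# per-sample coefficient read from the final step (a global map, suits the
# flattened-input feedforward net). Both are deterministic and noiseless,
# and samples differ strongly, so only a model that reads the input fits.
tiny_task <- function(mode = c("pointwise", "blend"), n = 80, C = 3, seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  A <- array(0, dim = c(n, C, 101))
  for (i in 1:n) for (c in 1:C) {
    A[i, c, ] <- minmax_normalize(cumsum(rnorm(101)))$values
  }
  Y <- if (mode == "pointwise") {
    0.1 + 0.8 * plogis(6 * (A[, 1, ] - 0.5))
  } else {
    shape1 <- exp(-((0:100) - 25)^2 / 72)
    shape2 <- exp(-((0:100) - 75)^2 / 72)
    a <- A[, 1, 101]
    0.1 + 0.8 * (outer(a, shape1) + outer(1 - a, shape2))
  }
  X <- t(vapply(1:n, function(i) as.vector(t(A[i, , ])), numeric(C * 101)))
  idx <- 1:60
  list(train = list(X = X[idx, ], A = A[idx, , ], Y = Y[idx, ]),
       val = list(X = X[-idx, ], A = A[-idx, , ], Y = Y[-idx, ]))
}

tiny_config <- function(arch, ...) {
  model_config(arch, hidden_layers = 1, hidden_units = 16, dropout_rate = 0,
               learning_rate = 1e-2, batch_size = 20, max_epochs = 80,
               early_stop_patience = 0, seed = 7, ...)
}

test_that("parameter counts equal the closed-form layer arithmetic", {
  fnn <- build_estimator(model_config("fnn"), c(101, 24))
  expect_equal(count_parameters(fnn),
               2424 * 256 + 256 + 3 * (256 * 256 + 256) + 256 * 101 + 101)
  lstm <- build_estimator(model_config("lstm", hidden_layers = 1, hidden_units = 8,
                                       lstm_head = "final"), c(101, 24))
  expect_equal(count_parameters(lstm), 4 * ((24 + 8) * 8 + 8) + (8 * 101 + 101))
  # stacked LSTM: later layers see H inputs
  lstm2 <- build_estimator(model_config("lstm", hidden_layers = 2, hidden_units = 8,
                                        lstm_head = "final"))
  expect_equal(count_parameters(lstm2),
               4 * ((24 + 8) * 8 + 8) + 4 * ((8 + 8) * 8 + 8) + (8 * 101 + 101))
  # shared per-step readout: one dense unit + scalar bias
  lstm3 <- build_estimator(model_config("lstm", hidden_layers = 1, hidden_units = 8))
  expect_equal(count_parameters(lstm3), 4 * ((24 + 8) * 8 + 8) + (8 + 1))
  expect_error(model_config("cnn"))
  expect_error(model_config("fnn", dropout_rate = 1))
  expect_error(model_config("fnn", hidden_activation = "relu"))
})

test_that("training fits a noiseless mapping and is bit-reproducible", {
  for (arch in c("fnn", "lstm")) {
    task <- tiny_task(if (arch == "fnn") "blend" else "pointwise")
    est0 <- build_estimator(tiny_config(arch), c(101, 3))
    expect_warning(P0 <- predict(est0, task$val), "untrained")
    init_mse <- mean((P0 - task$val$Y)^2)
    fit1 <- fit_estimator(est0, task$train, task$val)
    # >= 10x drop in validation MSE relative to the untrained net
    expect_lt(min(fit1$history$val_loss), init_mse / 10)
    # same seed, same data -> identical training history
    fit2 <- fit_estimator(est0, task$train, task$val)
    expect_identical(fit1$history, fit2$history)
  }
})

test_that("a constant target is fit to near-zero error by the bias path", {
  task <- tiny_task()
  task$train$Y[] <- 0.42
  task$val$Y[] <- 0.42
  fit <- fit_estimator(build_estimator(tiny_config("lstm"), c(101, 3)),
                       task$train, task$val)
  expect_lt(min(fit$history$val_loss), 1e-4)
})

test_that("label permutation destroys generalization (negative control)", {
  task <- tiny_task()
  fit_true <- fit_estimator(build_estimator(tiny_config("lstm"), c(101, 3)),
                            task$train, task$val)
  set.seed(2)
  task_perm <- task
  task_perm$train$Y <- task$train$Y[sample(nrow(task$train$Y)), ]
  fit_perm <- fit_estimator(build_estimator(tiny_config("lstm"), c(101, 3)),
                            task_perm$train, task_perm$val)
  expect_gt(min(fit_perm$history$val_loss), 3 * min(fit_true$history$val_loss))
})

test_that("predictions are bounded, batched consistently, order-preserving", {
  task <- tiny_task()
  est <- fit_estimator(build_estimator(tiny_config("lstm"), c(101, 3)),
                       task$train, task$val)
  P <- predict(est, task$val)
  expect_equal(dim(P), c(20, 101))
  expect_true(all(P > 0 & P < 1))

  # fuzz: extreme inputs still map into (0, 1)
  wild <- list(X = matrix(rnorm(5 * 303, 0, 50), 5),
               A = array(rnorm(5 * 3 * 101, 0, 50), c(5, 3, 101)))
  expect_true(all(predict(est, wild) > 0 & predict(est, wild) < 1))

  # batch-of-one equals the matching row of the batch; order is preserved
  # (tolerance reflects the single-precision LSTM core)
  one <- list(X = task$val$X[3, , drop = FALSE],
              A = task$val$A[3, , , drop = FALSE])
  expect_equal(as.numeric(predict(est, one)), P[3, ], tolerance = 1e-5)
  perm <- c(5, 1, 4, 2, 3)
  Pp <- predict(est, list(X = task$val$X[perm, ], A = task$val$A[perm, , ]))
  expect_equal(Pp, P[perm, ], tolerance = 1e-5)

  # repeated prediction with fixed weights is deterministic (dropout is
  # training-only)
  expect_identical(predict(est, task$val), P)

  est_f <- fit_estimator(build_estimator(tiny_config("fnn"), c(101, 3)),
                         task$train, task$val)
  Pf <- predict(est_f, task$val)
  expect_true(all(Pf > 0 & Pf < 1))
  expect_equal(as.numeric(predict(est_f, list(X = task$val$X[7, , drop = FALSE],
                                              A = task$val$A[7, , , drop = FALSE]))),
               Pf[7, ], tolerance = 1e-12)
})

test_that("checkpoints round-trip through disk with their sidecar", {
  task <- tiny_task()
  est <- fit_estimator(build_estimator(tiny_config("fnn"), c(101, 3)),
                       task$train, task$val, muscle = "soleus")
  path <- file.path(tempdir(), "ckpt.rds")
  save_estimator(est, path)
  back <- load_estimator(path)
  expect_equal(predict(back, task$val), predict(est, task$val))
  side <- yaml::read_yaml(sub("rds$", "yml", path))
  expect_equal(side$muscle, "soleus")
  expect_equal(side$architecture, "fnn")
  unlink(c(path, sub("rds$", "yml", path)))
})
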