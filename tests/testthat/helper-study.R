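# Shared fixtures for the study-level validation tests: the default
# 720-stride synthetic study (coupled sensors) and its decoupled
# negative-control twin are generated once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

validation_study <- function(coupled = TRUE, seed = 202) {
  key <- if (coupled) "coupled" else "decoupled"
  if (is.null(.study_cache[[key]])) {
    study <- generate_study(seed = seed, noise_imu = 0.02,
                            coupling = if (coupled) 1 else 0)
    samples <- build_study_samples(study)
    split <- split_dataset(samples, seed = seed)
    .study_cache[[key]] <- list(study = study, samples = samples, split = split)
  }
  .study_cache[[key]]
}

# reduced-size training profile used for the scaled-down learning checks;
# fixed epoch counts (no early stopping) keep the runtime deterministic
reduced_config <- function(arch, seed) {
  model_config(arch, hidden_layers = 2, hidden_units = 64, dropout_rate = 0.1,
               learning_rate = if (arch == "lstm") 2e-3 else 1e-3,
               batch_size = 64,
               max_epochs = if (arch == "lstm") 40L else 100L,
               early_stop_patience = 0L,
               seed = seed)
}

heldout_scores <- function(split, est, muscle) {
  mm <- samples_to_matrices(split$test, muscle)
  P <- predict(est, mm)
  rr <- vapply(seq_len(nrow(P)), function(i) pearson_r(mm$Y[i, ], P[i, ]), numeric(1))
  nr <- vapply(seq_len(nrow(P)), function(i) nrmse(mm$Y[i, ], P[i, ]), numeric(1))
  c(r = mean(rr, na.rm = TRUE), nrmse = mean(nr, na.rm = TRUE))
}
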