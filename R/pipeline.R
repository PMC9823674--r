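#' Default run configuration
#'
#' A nested list mirroring the YAML run-config schema. Blocks: `synthetic`
#' (study generation), `signal` (filter chain), `split` (dataset division),
#' `model` (architectures and training hyper-parameters), `muscles`, `seed`.
#' [validate_config()] rejects unknown keys before any computation.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    muscles = "all",
    synthetic = list(n_subjects = 4L, trials_per_subject = 3L,
                     strides_per_trial = 60L, coupling = 1,
                     noise_imu = 0.05, emg_noise = 0.01,
                     fs_emg = 1000, fs_imu = 200),
    signal = list(bandpass_low_hz = 20, bandpass_high_hz = 400,
                  envelope_cutoff_hz = 8, filter_order = 4,
                  median_kernel = 5, n_points = 101,
                  stride_min_s = 0.4, stride_max_s = 2.5),
    split = list(ratios = c(0.80, 0.15, 0.05), by = "stride",
                 unseen_subject = "auto"),
    model = list(architectures = c("fnn", "lstm"),
                 hidden_layers = 4L, hidden_units = 256L,
                 dropout_rate = 0.2, learning_rate = 1e-3,
                 batch_size = 32L, max_epochs = 300L,
                 early_stop_patience = 25L)
  )
}

#' Validate a run configuration against the schema
#'
#' Checks that every key is known (unknown keys are rejected, catching typos
#' before compute time), fills omitted keys with their defaults, and
#' sanity-checks value types and ranges.
#'
#' @param config Nested list, e.g. from [read_config()].
#' @return The completed configuration (invisibly usable downstream).
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_block <- function(cfg, ref, path = "") {
    unknown <- setdiff(names(cfg), names(ref))
    if (length(unknown)) {
      stop("config: unknown key(s) ", paste0(path, unknown, collapse = ", "))
    }
    for (k in names(ref)) {
      if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
        cfg[[k]] <- check_block(if (is.null(cfg[[k]])) list() else cfg[[k]],
                                ref[[k]], paste0(path, k, "."))
      } else if (is.null(cfg[[k]])) {
        cfg[[k]] <- ref[[k]]
      }
    }
    cfg
  }
  config <- check_block(config, ref)
  if (abs(sum(config$split$ratios) - 1) > 1e-8) stop("config: split.ratios must sum to 1")
  if (!all(config$model$architectures %in% c("fnn", "lstm"))) {
    stop("config: model.architectures must be a subset of {fnn, lstm}")
  }
  config
}

#' Read and validate a YAML run configuration
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_muscles <- function(config) {
  if (identical(config$muscles, "all")) muscle_names() else config$muscles
}

stage_done <- function(run_dir, stage, fingerprint) {
  f <- file.path(run_dir, "stages", paste0(stage, ".json"))
  file.exists(f) && identical(jsonlite::read_json(f)$fingerprint, fingerprint)
}

stage_mark <- function(run_dir, stage, fingerprint) {
  d <- file.path(run_dir, "stages")
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  jsonlite::write_json(list(fingerprint = fingerprint, at = format(Sys.time())),
                       file.path(run_dir, "stages", paste0(stage, ".json")),
                       auto_unbox = TRUE)
}

fingerprint <- function(...) {
  # stable content hash of the stage-relevant config
  x <- paste(utils::capture.output(utils::str(list(...), digits.d = 12)), collapse = "\n")
  as.character(stable_hash(x))
}

log_line <- function(run_dir, ...) {
  cat(format(Sys.time(), "%H:%M:%S "), sprintf(...), "\n", sep = "",
      file = file.path(run_dir, "run_log.txt"), append = TRUE)
}

#' Run the full pipeline: simulate, preprocess, split, train, predict,
#' evaluate, reconstruct
#'
#' Orchestrates an end-to-end run into `run_dir` with a deterministic
#' artifact layout: `data/` (trial files), `cycles.rds` (processed samples),
#' `split_manifest.csv`, `models/` (checkpoints + YAML sidecars),
#' `predictions/`, `report.csv`/`report.json`, `reconstructed/`, and
#' `run_log.txt` recording seeds, package versions and the effective
#' configuration. Stages are idempotent: a stage whose outputs already exist
#' under an unchanged configuration fingerprint is skipped, so interrupted
#' runs resume where they stopped.
#'
#' @param config A configuration list (see [default_config()]); validated
#'   before any computation.
#' @param run_dir Output directory.
#' @return Invisibly, a list with the evaluation `report`, the `split`, and
#'   the trained model paths.
#' @export
run_pipeline <- function(config = default_config(), run_dir) {
  config <- validate_config(config)
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  yaml::write_yaml(config, file.path(run_dir, "effective_config.yml"))
  log_line(run_dir, "run started; seed %d; gaitemg %s; R %s", config$seed,
           as.character(utils::packageVersion("gaitemg")),
           paste(R.version$major, R.version$minor, sep = "."))
  muscles <- config_muscles(config)

  # ---- simulate
  fp <- fingerprint(config$synthetic, config$seed)
  data_dir <- file.path(run_dir, "data")
  if (!stage_done(run_dir, "simulate", fp)) {
    study <- do.call(generate_study, c(config$synthetic, list(seed = config$seed)))
    write_study(study, data_dir)
    saveRDS(study, file.path(run_dir, "study.rds"))
    stage_mark(run_dir, "simulate", fp)
    log_line(run_dir, "simulate: %d trials", length(study$trials))
  } else {
    study <- readRDS(file.path(run_dir, "study.rds"))
    log_line(run_dir, "simulate: skipped (up to date)")
  }

  # ---- preprocess
  fp <- fingerprint(config$synthetic, config$signal, config$seed)
  cyc_path <- file.path(run_dir, "cycles.rds")
  if (!stage_done(run_dir, "preprocess", fp)) {
    samples <- build_study_samples(
      study, muscles = muscles,
      low_hz = config$signal$bandpass_low_hz,
      high_hz = config$signal$bandpass_high_hz,
      envelope_hz = config$signal$envelope_cutoff_hz,
      order = config$signal$filter_order,
      median_kernel = config$signal$median_kernel,
      stride_min_s = config$signal$stride_min_s,
      stride_max_s = config$signal$stride_max_s)
    saveRDS(samples, cyc_path)
    stage_mark(run_dir, "preprocess", fp)
    log_line(run_dir, "preprocess: %d gait-cycle samples", length(samples))
  } else {
    samples <- readRDS(cyc_path)
    log_line(run_dir, "preprocess: skipped (up to date)")
  }

  # ---- split
  unseen <- config$split$unseen_subject
  if (identical(unseen, "auto")) {
    ids <- sort(unique(vapply(samples, `[[`, character(1), "subject_id")))
    old <- .Random.seed_save(); set.seed(config$seed)
    unseen <- sample(ids, 1)
    .Random.seed_restore(old)
  }
  split <- split_dataset(samples, ratios = config$split$ratios,
                         seed = config$seed, by = config$split$by,
                         unseen_subject = unseen)
  data.table::fwrite(split_manifest(split), file.path(run_dir, "split_manifest.csv"))
  log_line(run_dir, "split: train %d / val %d / test %d / unseen %d (subject %s)",
           length(split$train), length(split$validation), length(split$test),
           length(split$unseen_subject), unseen)

  # ---- train / predict / evaluate / reconstruct
  model_dir <- file.path(run_dir, "models")
  pred_dir <- file.path(run_dir, "predictions")
  rec_dir <- file.path(run_dir, "reconstructed")
  for (d in c(model_dir, pred_dir, rec_dir)) if (!dir.exists(d)) dir.create(d)

  fp <- fingerprint(config, "train")
  report <- list()
  model_paths <- character()
  for (arch in config$model$architectures) {
    for (m in muscles) {
      ckpt <- file.path(model_dir, paste0(arch, "_", m, ".rds"))
      cfg <- model_config(architecture = arch,
                          hidden_layers = config$model$hidden_layers,
                          hidden_units = config$model$hidden_units,
                          dropout_rate = config$model$dropout_rate,
                          learning_rate = config$model$learning_rate,
                          batch_size = config$model$batch_size,
                          max_epochs = config$model$max_epochs,
                          early_stop_patience = config$model$early_stop_patience,
                          seed = config$seed)
      if (file.exists(ckpt) && stage_done(run_dir, paste0("train_", arch, "_", m), fp)) {
        est <- load_estimator(ckpt)
        log_line(run_dir, "train %s/%s: skipped (up to date)", arch, m)
      } else {
        est <- build_estimator(cfg)
        est <- train_estimator(est, split, m)
        save_estimator(est, ckpt)
        stage_mark(run_dir, paste0("train_", arch, "_", m), fp)
        log_line(run_dir, "train %s/%s: best epoch %d, val MSE %.3g", arch, m,
                 est$best_epoch, min(est$history$val_loss))
      }
      model_paths <- c(model_paths, ckpt)

      for (grp in c("test", "unseen")) {
        ss <- if (grp == "test") split$test else split$unseen_subject
        if (!length(ss)) next
        mm <- samples_to_matrices(ss, m)
        P <- predict(est, mm)
        data.table::fwrite(as.data.frame(P),
                           file.path(pred_dir, paste0(arch, "_", m, "_", grp, ".csv")))
        row <- evaluate_group(mm$Y, P, muscle = m, group = grp)
        row$architecture <- arch
        report[[length(report) + 1L]] <- row
      }
    }
  }
  report <- do.call(rbind, report)
  write_report(report, run_dir)
  log_line(run_dir, "evaluate: %d report rows", nrow(report))

  # ---- reconstruct: continuous predicted envelope for the first test trial
  if (length(split$test)) {
    s0 <- split$test[[1]]
    tr <- Filter(function(tr) tr$subject_id == s0$subject_id &&
                   tr$trial_id == s0$trial_id, study$trials)[[1]]
    arch <- config$model$architectures[[1]]
    for (m in muscles[1]) {
      est <- load_estimator(file.path(model_dir, paste0(arch, "_", m, ".rds")))
      ss <- build_samples(tr, muscles = m,
                          low_hz = config$signal$bandpass_low_hz,
                          high_hz = config$signal$bandpass_high_hz,
                          envelope_hz = config$signal$envelope_cutoff_hz,
                          order = config$signal$filter_order,
                          median_kernel = config$signal$median_kernel)
      mm <- samples_to_matrices(ss, m)
      P <- predict(est, mm)
      cycles <- lapply(seq_len(nrow(P)), function(i)
        normalized_cycle(P[i, ], params = mm$params[[i]],
                         start_s = ss[[i]]$start_s, end_s = ss[[i]]$end_s,
                         channel = paste0("emg_", m)))
      rec <- reconstruct_time_domain(cycles, tr$events, fs_out = 100)
      data.table::fwrite(data.frame(time_s = signal_times(rec), value = rec$samples),
                         file.path(rec_dir, paste0(arch, "_", m, "_",
                                                   tr$subject_id, "_", tr$trial_id, ".csv")))
    }
    log_line(run_dir, "reconstruct: wrote continuous predictions")
  }

  log_line(run_dir, "run finished")
  invisible(list(report = report, split = split, models = model_paths))
}
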