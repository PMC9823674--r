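#' Canonical IMU channel order
#'
#' Feature columns are always arranged segment-major: trunk, thigh, shank,
#' foot, each contributing accelerometer x, y, z then gyroscope x, y, z —
#' 24 channels in total. Readers map channels by *name*, so the column order
#' of input files is irrelevant.
#'
#' @return Character vector of 24 channel names.
#' @export
imu_channel_order <- function() {
  segs <- c("trunk", "thigh", "shank", "foot")
  sensors <- c("accel", "gyro")
  axes <- c("x", "y", "z")
  as.vector(vapply(segs, function(s)
    as.vector(vapply(sensors, function(m) paste(s, m, axes, sep = "_"),
                     character(3))), character(6)))
}

#' Default muscle channel names
#'
#' The nine lower-extremity muscles estimated by this package. EMG columns in
#' trial files are named `emg_<muscle>`.
#'
#' @return Character vector of 9 muscle names.
#' @export
muscle_names <- function() {
  c("gastrocnemius", "tibialis_anterior", "soleus",
    "vastus_medialis", "vastus_lateralis", "rectus_femoris",
    "biceps_femoris", "semitendinosus", "gluteus_medius")
}

trial_channel_list <- function(x, what = "imu") {
  # accept either a named list of raw_signal (from read_trial) or a
  # data.frame with a time_s column (from generate_study)
  if (is.data.frame(x)) {
    tm <- x$time_s
    fs <- 1 / stats::median(diff(tm))
    chans <- setdiff(names(x), "time_s")
    out <- lapply(chans, function(ch) raw_signal(x[[ch]], fs = fs, label = ch, t0 = tm[1]))
    names(out) <- chans
    return(out)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "raw_signal"))) return(x)
  stop("cannot interpret trial ", what, " block")
}

#' Build per-stride feature/target samples from one trial
#'
#' Runs the complete preprocessing for a trial: conditions every EMG channel
#' into an activation envelope, segments all channels at the heel strikes,
#' time-normalizes to 101 phase points, median-filters and min-max
#' normalizes per stride, and assembles one sample per stride: a 101 x 24
#' feature block (channels in [imu_channel_order()]) and one 101-point
#' normalized envelope per muscle. Strides with physiologically implausible
#' duration (outside `stride_min_s`--`stride_max_s`) are excluded.
#'
#' @param trial A trial list (`imu`, `emg`, `events`, `subject_id`,
#'   `trial_id`, `speed`) from [generate_study()] or [read_trial()].
#' @param muscles Muscle names to extract (default all present).
#' @param low_hz,high_hz,envelope_hz,order EMG chain parameters, see
#'   [process_emg()].
#' @param median_kernel Median-filter window on the 101-point arrays.
#' @param stride_min_s,stride_max_s Plausible stride-duration band (s);
#'   strides outside it are dropped from the training data.
#' @return List of `gait_cycle_sample` objects.
#' @export
build_samples <- function(trial, muscles = NULL,
                          low_hz = 20, high_hz = 400, envelope_hz = 8,
                          order = 4, median_kernel = 5,
                          stride_min_s = 0.4, stride_max_s = 2.5) {
  imu <- trial_channel_list(trial$imu, "imu")
  emg <- trial_channel_list(trial$emg, "emg")
  need <- imu_channel_order()
  missing_ch <- setdiff(need, names(imu))
  if (length(missing_ch)) {
    stop("trial '", trial$trial_id, "' is missing IMU channel(s): ",
         paste(missing_ch, collapse = ", "))
  }
  if (is.null(muscles)) {
    muscles <- sub("^emg_", "", grep("^emg_", names(emg), value = TRUE))
  }
  miss_m <- setdiff(paste0("emg_", muscles), names(emg))
  if (length(miss_m)) {
    stop("trial '", trial$trial_id, "' is missing EMG channel(s): ",
         paste(miss_m, collapse = ", "))
  }
  hs <- trial$events

  imu_cycles <- lapply(need, function(ch)
    normalize_cycles(imu[[ch]], hs, median_kernel = median_kernel))
  names(imu_cycles) <- need
  emg_cycles <- lapply(muscles, function(m) {
    env <- process_emg(emg[[paste0("emg_", m)]], low_hz = low_hz,
                       high_hz = high_hz, envelope_hz = envelope_hz, order = order)
    normalize_cycles(env, hs, median_kernel = median_kernel)
  })
  names(emg_cycles) <- muscles

  n_strides <- length(imu_cycles[[1]])
  stopifnot(all(vapply(imu_cycles, length, integer(1)) == n_strides),
            all(vapply(emg_cycles, length, integer(1)) == n_strides))

  samples <- list()
  for (k in seq_len(n_strides)) {
    ref <- imu_cycles[[1]][[k]]
    dur <- ref$end_s - ref$start_s
    if (dur < stride_min_s || dur > stride_max_s) next  # implausible stride
    feats <- vapply(need, function(ch) imu_cycles[[ch]][[k]]$values, numeric(101))
    targets <- lapply(muscles, function(m) emg_cycles[[m]][[k]])
    names(targets) <- muscles
    samples[[length(samples) + 1L]] <- structure(
      list(features = feats, targets = targets,
           subject_id = trial$subject_id, trial_id = trial$trial_id,
           stride_index = k, speed = trial$speed,
           start_s = ref$start_s, end_s = ref$end_s),
      class = "gait_cycle_sample")
  }
  samples
}

#' Build samples for a whole study
#'
#' @param study A list of trials (e.g. [generate_study()]`$trials`).
#' @param ... Passed to [build_samples()].
#' @return Flat list of `gait_cycle_sample` objects over all trials.
#' @export
build_study_samples <- function(study, ...) {
  trials <- if (!is.null(study$trials)) study$trials else study
  unlist(lapply(trials, build_samples, ...), recursive = FALSE)
}

#' Random train/validation/test split of gait-cycle samples
#'
#' Randomizes samples and divides them 80:15:5 (by default) into training,
#' validation and test groups. Validation and test sizes are rounded down;
#' the remainder goes to training. The default unit of randomization is the
#' individual stride (cycles of one subject may appear in several groups);
#' `by = "trial"` keeps whole trials together instead. An unseen subject can
#' be excluded up front and carried alongside the split.
#'
#' @param samples List of `gait_cycle_sample` objects (>= 20).
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed; the split is fully reproducible given the seed.
#' @param by `"stride"` (default) or `"trial"`.
#' @param unseen_subject Optional subject id to hold out entirely before
#'   splitting (see [holdout_subject()]).
#' @return Object of class `dataset_split`: lists `train`, `validation`,
#'   `test`, `unseen_subject`, plus `seed` and `by`.
#' @export
split_dataset <- function(samples, ratios = c(0.80, 0.15, 0.05), seed = 1,
                          by = c("stride", "trial"), unseen_subject = NULL) {
  by <- match.arg(by)
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3L || any(ratios < 0)) {
    stop("split_dataset: ratios must be three non-negative numbers summing to 1")
  }
  unseen <- list()
  if (!is.null(unseen_subject)) {
    hd <- holdout_subject(samples, unseen_subject)
    samples <- hd$remaining
    unseen <- hd$unseen
  }
  n <- length(samples)
  if (n < 20L) stop("split_dataset: need at least 20 samples, got ", n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  if (by == "stride") {
    perm <- sample.int(n)
    n_val <- floor(ratios[2] * n)
    n_test <- floor(ratios[3] * n)
    n_train <- n - n_val - n_test
    idx_train <- perm[seq_len(n_train)]
    idx_val <- perm[n_train + seq_len(n_val)]
    idx_test <- perm[n_train + n_val + seq_len(n_test)]
    sp <- list(train = samples[idx_train], validation = samples[idx_val],
               test = samples[idx_test])
  } else {
    keys <- vapply(samples, function(s) paste(s$subject_id, s$trial_id), character(1))
    trials <- sample(unique(keys))
    counts <- vapply(trials, function(k) sum(keys == k), integer(1))
    cum <- cumsum(counts) / n
    # whole trials assigned in shuffled order until each group's quota is met
    grp <- cut(cum - counts / (2 * n), breaks = c(0, ratios[1], ratios[1] + ratios[2], 1),
               labels = c("train", "validation", "test"), include.lowest = TRUE)
    sp <- lapply(c(train = "train", validation = "validation", test = "test"),
                 function(g) samples[keys %in% trials[grp == g]])
  }
  structure(c(sp, list(unseen_subject = unseen, seed = seed, by = by)),
            class = "dataset_split")
}

#' Hold out one subject entirely
#'
#' @param samples List of `gait_cycle_sample` objects.
#' @param subject_id Subject to exclude; must be present.
#' @return List with `remaining` and `unseen` sample lists.
#' @export
holdout_subject <- function(samples, subject_id) {
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  if (!subject_id %in% ids) {
    stop("holdout_subject: subject '", subject_id, "' not present in the data")
  }
  list(remaining = samples[ids != subject_id],
       unseen = samples[ids == subject_id])
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split by %s, seed %d: train %d / validation %d / test %d, unseen %d>\n",
              x$by, x$seed, length(x$train), length(x$validation),
              length(x$test), length(x$unseen_subject)))
  invisible(x)
}

#' Split manifest as a text table
#'
#' @param split A `dataset_split`.
#' @return `data.frame` with one row per sample: subject, trial, stride index
#'   and assigned group — written alongside pipeline runs for auditability.
#' @export
split_manifest <- function(split) {
  one <- function(group) {
    ss <- split[[group]]
    if (!length(ss)) return(NULL)
    data.frame(subject_id = vapply(ss, `[[`, character(1), "subject_id"),
               trial_id = vapply(ss, `[[`, character(1), "trial_id"),
               stride_index = vapply(ss, `[[`, integer(1), "stride_index"),
               group = group, stringsAsFactors = FALSE)
  }
  do.call(rbind, Filter(Negate(is.null),
                        lapply(c("train", "validation", "test", "unseen_subject"), one)))
}

#' Feature/target matrices for one muscle
#'
#' Converts a sample list to the shapes the estimators consume: `X` flattens
#' each 101 x 24 block column-major (channel-blocks of 101 phase points, so
#' 2424 inputs for the feedforward net), `A` keeps the sequence layout as an
#' `n x 24 x 101` array (24-channel vector per phase step for the LSTM), and
#' `Y` holds the 101-point normalized envelope of `muscle`.
#'
#' @param samples List of `gait_cycle_sample` objects.
#' @param muscle Muscle name, or a vector of names for the multi-output
#'   variant (one estimator predicting several muscles): the target blocks
#'   are concatenated, giving `Y` of width `101 * length(muscle)`; pair this
#'   with `build_estimator(..., n_outputs = 101 * M)` and the feedforward
#'   architecture (or the final-state LSTM head).
#' @return List with `X` (n x 2424), `A` (n x 24 x 101), `Y` (n x 101 per
#'   muscle), and `params` (per-sample [norm_params()] of the target cycles;
#'   a list of per-muscle lists when several muscles are requested).
#' @export
samples_to_matrices <- function(samples, muscle) {
  n <- length(samples)
  if (!n) stop("samples_to_matrices: empty sample list")
  missing_m <- setdiff(muscle, names(samples[[1]]$targets))
  if (length(missing_m)) {
    stop("samples_to_matrices: no target envelope for muscle '",
         paste(missing_m, collapse = "', '"), "'")
  }
  X <- t(vapply(samples, function(s) as.vector(s$features), numeric(101 * 24)))
  A <- array(0, dim = c(n, 24, 101))
  for (i in seq_len(n)) A[i, , ] <- t(samples[[i]]$features)
  Y <- do.call(cbind, lapply(muscle, function(m)
    t(vapply(samples, function(s) s$targets[[m]]$values, numeric(101)))))
  params <- if (length(muscle) == 1L) {
    lapply(samples, function(s) s$targets[[muscle]]$params)
  } else {
    stats::setNames(lapply(muscle, function(m)
      lapply(samples, function(s) s$targets[[m]]$params)), muscle)
  }
  list(X = X, A = A, Y = Y, params = params)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
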