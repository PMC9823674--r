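#' Construct a raw single-channel signal
#'
#' Container for one uniformly sampled channel (EMG or one IMU axis). Time of
#' sample `i` (1-based) is `t0 + (i - 1) / fs`.
#'
#' @param samples Numeric vector of samples; must be finite, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name, e.g. `"emg_soleus"` or `"shank_gyro_z"`.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return An object of class `raw_signal`.
#' @export
raw_signal <- function(samples, fs, label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("raw_signal: need at least 2 samples, got ", length(samples))
  }
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("raw_signal: channel '", label, "' contains missing or non-finite values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("raw_signal: fs must be a positive scalar (Hz)")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs), label = as.character(label),
         t0 = as.numeric(t0)),
    class = "raw_signal"
  )
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal '%s': %d samples @ %g Hz, t0 = %g s, span %.3f s>\n",
              x$label, length(x$samples), x$fs, x$t0, signal_duration(x)))
  invisible(x)
}

#' @export
length.raw_signal <- function(x) length(x$samples)

#' Sample times of a raw signal
#' @param x A `raw_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "raw_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

signal_duration <- function(x) (length(x$samples) - 1) / x$fs

as_raw_signal <- function(x, fs = NULL, label = "signal", t0 = 0) {
  if (inherits(x, "raw_signal")) return(x)
  if (is.null(fs)) stop("fs required to promote a numeric vector to raw_signal")
  raw_signal(x, fs = fs, label = label, t0 = t0)
}

# ---- delimited trial file I/O ------------------------------------------------

#' Read one channel table of a walking trial
#'
#' Trials are stored as delimited files with a `time_s` column plus named
#' channels (`emg_<muscle>` or `<segment>_<accel|gyro>_<x|y|z>`). The sampling
#' rate is inferred from the time column; recordings whose sample spacing
#' jitters by more than 1% of the median interval are rejected, as are tables
#' with missing values.
#'
#' @param path Path to a delimited text file.
#' @return A list of `raw_signal` objects, one per channel, plus the inferred
#'   sampling rate as attribute `fs`.
#' @export
read_channels <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!"time_s" %in% names(dt)) stop("file ", path, " has no 'time_s' column")
  if (anyNA(dt)) stop("file ", path, " contains missing values; refusing to impute silently")
  tm <- dt$time_s
  dts <- diff(tm)
  med <- stats::median(dts)
  if (med <= 0) stop("file ", path, ": time column is not strictly increasing")
  if (max(abs(dts - med)) > 0.01 * med) {
    stop("file ", path, ": irregular sampling (jitter > 1% of median interval)")
  }
  fs <- 1 / med
  chans <- setdiff(names(dt), "time_s")
  out <- lapply(chans, function(ch) raw_signal(dt[[ch]], fs = fs, label = ch, t0 = tm[1]))
  names(out) <- chans
  attr(out, "fs") <- fs
  out
}

#' Read a heel-strike events file
#'
#' @param path Delimited file with one `heel_strike_s` column.
#' @return Ascending numeric vector of heel-strike times in seconds.
#' @export
read_events <- function(path) {
  dt <- data.table::fread(path, data.table = FALSE)
  if (!"heel_strike_s" %in% names(dt)) stop("file ", path, " has no 'heel_strike_s' column")
  hs <- as.numeric(dt$heel_strike_s)
  if (anyNA(hs)) stop("events file ", path, " contains missing values")
  if (is.unsorted(hs, strictly = TRUE)) stop("heel-strike times must be strictly ascending")
  hs
}

#' Read a full walking trial from disk
#'
#' Expects `<prefix>_imu.csv`, `<prefix>_emg.csv` and `<prefix>_events.csv`
#' under `dir`, in the format written by [write_trial()].
#'
#' @param dir Directory holding the trial files.
#' @param prefix File prefix, typically `"<subject>_<trial>"`.
#' @return A trial list with elements `imu`, `emg` (channel lists as returned
#'   by [read_channels()]), `events`, `subject_id`, `trial_id`, `speed`.
#' @export
read_trial <- function(dir, prefix) {
  imu <- read_channels(file.path(dir, paste0(prefix, "_imu.csv")))
  emg <- read_channels(file.path(dir, paste0(prefix, "_emg.csv")))
  events <- read_events(file.path(dir, paste0(prefix, "_events.csv")))
  meta_path <- file.path(dir, paste0(prefix, "_meta.csv"))
  meta <- if (file.exists(meta_path)) {
    data.table::fread(meta_path, data.table = FALSE)
  } else {
    data.frame(subject_id = NA_character_, trial_id = prefix, speed = NA_character_)
  }
  list(imu = imu, emg = emg, events = events,
       subject_id = meta$subject_id[1], trial_id = meta$trial_id[1],
       speed = meta$speed[1])
}

#' Write a trial to delimited files
#'
#' Writes `<prefix>_imu.csv`, `<prefix>_emg.csv`, `<prefix>_events.csv` and a
#' small `<prefix>_meta.csv` under `dir`. Output is deterministic: the same
#' trial always produces byte-identical files.
#'
#' @param trial A trial as produced by [generate_study()] (elements `imu`,
#'   `emg` as data frames with a `time_s` column, `events`, ids).
#' @param dir Output directory (created if absent).
#' @param prefix File prefix; defaults to `"<subject_id>_<trial_id>"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_trial <- function(trial, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- paste0(trial$subject_id, "_", trial$trial_id)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_imu.csv", "_emg.csv", "_events.csv", "_meta.csv")))
  data.table::fwrite(signif_df(trial$imu), paths[1])
  data.table::fwrite(signif_df(trial$emg), paths[2])
  data.table::fwrite(data.frame(heel_strike_s = trial$events), paths[3])
  data.table::fwrite(data.frame(subject_id = trial$subject_id,
                                trial_id = trial$trial_id,
                                speed = trial$speed), paths[4])
  invisible(paths)
}

# round to a fixed number of significant digits so files are compact and
# platform-stable; 10 digits is far below any tolerance used downstream
signif_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 10)
  df
}
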