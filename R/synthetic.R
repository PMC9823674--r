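#' Synthetic muscle activation specification
#'
#' Describes the stereotyped activation profile of one muscle as a sum of
#' Gaussian bursts on the circular 0--100% gait-cycle phase axis (bursts near
#' 100% wrap into the next cycle's early phase). Each burst may carry its own
#' amplitude multiplier per walking-speed class, which is how speed-dependent
#' features (e.g. a stance-phase hamstring burst that is strongest in slow
#' walking, or a rectus femoris swing burst that grows with speed) are
#' expressed. Optional crosstalk adds a fraction of a neighbouring muscle's
#' activation, mimicking surface-electrode contamination.
#'
#' @param name Muscle name.
#' @param bursts List of bursts; each a list with `center` (% cycle, 0-100),
#'   `width` (% cycle, > 0), `amp` (>= 0) and optional `speed` (named
#'   multipliers for `slow`, `normal`, `fast`).
#' @param crosstalk Optional list `(source = <muscle>, fraction = <f>)`.
#' @return Object of class `muscle_spec`.
#' @export
muscle_spec <- function(name, bursts, crosstalk = NULL) {
  for (b in bursts) {
    if (b$center < 0 || b$center > 100) stop("muscle_spec: burst center must be in [0, 100]")
    if (b$width <= 0) stop("muscle_spec: burst width must be positive")
    if (b$amp < 0) stop("muscle_spec: burst amplitude must be non-negative")
  }
  structure(list(name = name, bursts = bursts, crosstalk = crosstalk),
            class = "muscle_spec")
}

#' Default specifications for the nine modelled muscles
#'
#' Burst phases follow standard gait-EMG timing: plantarflexors peak in late
#' stance (~45%), tibialis anterior fires in early swing (60-80%) and again
#' around heel strike (wrapping 90%-10%), the vasti and gluteus medius act in
#' loading response (~10-15%), hamstrings peak at terminal swing (~90%) with
#' an additional stance burst (~30%) that is largest in slow walking, and
#' rectus femoris has a speed-dependent pre-/initial-swing burst (~50%) plus
#' an early-stance component modelled as crosstalk from vastus lateralis.
#' The exact numbers are generator parameters, not measured quantities.
#'
#' @return Named list of [muscle_spec()] objects.
#' @export
default_muscle_specs <- function() {
  b <- function(center, width, amp, speed = NULL) {
    list(center = center, width = width, amp = amp, speed = speed)
  }
  specs <- list(
    muscle_spec("gastrocnemius",
                list(b(45, 9, 1.0, c(slow = 0.9, normal = 1, fast = 1.1)))),
    muscle_spec("soleus",
                list(b(47, 10, 1.0, c(slow = 0.9, normal = 1, fast = 1.1)))),
    muscle_spec("tibialis_anterior",
                list(b(70, 8, 1.0), b(97, 7, 0.8))),
    muscle_spec("vastus_medialis",
                list(b(13, 8, 1.0, c(slow = 0.9, normal = 1, fast = 1.15)))),
    muscle_spec("vastus_lateralis",
                list(b(12, 8, 1.0, c(slow = 0.9, normal = 1, fast = 1.15)))),
    muscle_spec("rectus_femoris",
                list(b(50, 9, 0.7, c(slow = 0.15, normal = 1, fast = 1.6))),
                crosstalk = list(source = "vastus_lateralis", fraction = 0.35)),
    muscle_spec("biceps_femoris",
                list(b(92, 8, 1.0), b(30, 9, 0.5, c(slow = 1.5, normal = 1, fast = 0.6)))),
    muscle_spec("semitendinosus",
                list(b(90, 8, 1.0), b(30, 9, 0.5, c(slow = 1.5, normal = 1, fast = 0.6)))),
    muscle_spec("gluteus_medius",
                list(b(10, 12, 1.0), b(85, 10, 0.4)))
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# signed circular phase distance in (-50, 50]
circ_dist <- function(phase, center) {
  ((phase - center + 50) %% 100) - 50
}

eval_bursts <- function(bursts, phase) {
  out <- numeric(length(phase))
  for (b in bursts) {
    d <- circ_dist(phase, b$center)
    out <- out + b$amp * exp(-d^2 / (2 * b$width^2))
  }
  out
}

eval_bursts_deriv <- function(bursts, phase) {
  out <- numeric(length(phase))
  for (b in bursts) {
    d <- circ_dist(phase, b$center)
    out <- out - (d / b$width^2) * b$amp * exp(-d^2 / (2 * b$width^2))
  }
  out
}

speed_mult <- function(burst, speed) {
  if (is.null(burst$speed)) 1 else unname(burst$speed[[speed]])
}

#' Stereotyped activation profile of a muscle
#'
#' Evaluates the noise-free, unjittered activation profile of a muscle spec
#' on a phase grid: the sum of its circular Gaussian bursts, each scaled by
#' its speed-class multiplier, on top of a small tonic baseline, clipped at
#' zero. Per-stride stochastic modulation is applied separately by the study
#' generator.
#'
#' @param spec A [muscle_spec()].
#' @param phase_pct Phase grid in percent of the gait cycle (0-100).
#' @param speed `"slow"`, `"normal"` or `"fast"`.
#' @param baseline Tonic resting activation (default 0.05).
#' @return Numeric envelope, same length as `phase_pct`, >= 0.
#' @export
activation_profile <- function(spec, phase_pct = 0:100, speed = "normal",
                               baseline = 0.05) {
  stopifnot(inherits(spec, "muscle_spec"))
  bursts <- lapply(spec$bursts, function(b) {
    b$amp <- b$amp * speed_mult(b, speed); b
  })
  pmax(eval_bursts(bursts, phase_pct) + baseline, 0)
}

# Per-stride realization: burst centers wander circularly (uniform +-50%
# cycle around their stereotyped phase, i.e. timing is stride-specific),
# gains vary mildly (lognormal), and one extra bounded random bump is added.
# The stride-to-stride variability is carried almost entirely by TIMING:
# that makes the variability dominate the stereotyped mean profile (so a
# model trained on decoupled sensors cannot score well by predicting the
# mean shape) while keeping each stride's amplitude range stable (so the
# per-stride min-max normalization is a near-constant affine map and the
# estimation task stays well conditioned). See the methods vignette: this
# deliberately exaggerates the timing variability of real gait.
realize_bursts <- function(spec, speed, center_jitter = 50, gain_sdlog = 0.1,
                           extra_bump_amp = c(0.25, 0.6), n_extra = 1L) {
  out <- lapply(spec$bursts, function(b) {
    list(center = (b$center + stats::runif(1, -center_jitter, center_jitter)) %% 100,
         width = b$width,
         amp = b$amp * speed_mult(b, speed) * stats::rlnorm(1, 0, gain_sdlog))
  })
  base_amp <- max(vapply(spec$bursts, `[[`, numeric(1), "amp"))
  for (i in seq_len(n_extra)) {
    out[[length(out) + 1L]] <- list(center = stats::runif(1, 0, 100),
                                    width = stats::runif(1, 6, 10),
                                    amp = stats::runif(1, extra_bump_amp[1], extra_bump_amp[2]) * base_amp)
  }
  out
}

#' Synthetic subject configuration
#'
#' Per-subject parameters: stride-period statistics, per-muscle amplitude
#' scaling, per-channel IMU gain/offset perturbations, and the subject's
#' smooth periodic IMU carriage (a low-order Fourier basis over the gait
#' phase with subject-specific coefficients). Drawn from a seeded substream
#' derived by stable hashing of the subject id, so subjects are reproducible
#' individually.
#'
#' @param subject_id Subject identifier string.
#' @param seed Study seed.
#' @return List of subject parameters.
#' @export
subject_config <- function(subject_id, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  n_ch <- 24L
  # healthy-gait kinematics are strongly stereotyped across people: every
  # subject's periodic carriage is a study-level template waveform plus a
  # modest subject-specific deviation
  set.seed(stable_hash("basis-template", seed))
  scales <- diag(c(1, 0.5, 0.25))
  template_cos <- matrix(stats::rnorm(n_ch * 3), n_ch, 3) %*% scales
  template_sin <- matrix(stats::rnorm(n_ch * 3), n_ch, 3) %*% scales
  set.seed(stable_hash("subject", seed, subject_id))
  list(
    subject_id = subject_id,
    stride_period_s = 1.1 + stats::rnorm(1, 0, 0.05),
    stride_jitter_s = 0.03,
    muscle_scale = stats::setNames(stats::runif(9, 0.8, 1.2), muscle_names()),
    imu_gain = stats::runif(n_ch, 0.9, 1.1),
    imu_offset = stats::rnorm(n_ch, 0, 0.2),
    fourier_cos = template_cos +
      0.25 * matrix(stats::rnorm(n_ch * 3), n_ch, 3) %*% scales,
    fourier_sin = template_sin +
      0.25 * matrix(stats::rnorm(n_ch * 3), n_ch, 3) %*% scales
  )
}

# deterministic 31-bit hash of arbitrary scalars, for seed substreams
stable_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "\r")
  h <- 0
  M <- 2147483647
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% M
  as.integer(h)
}

speed_period_factor <- c(slow = 1.15, normal = 1.0, fast = 0.87)
speed_basis_amp <- c(slow = 0.85, normal = 1.0, fast = 1.2)

#' IMU channels from activations and gait phase
#'
#' Builds the 24 IMU channels for one trial sample grid: each channel is the
#' subject's smooth periodic Fourier basis over the gait phase (amplitude
#' scaled by speed class) plus a linear mixture of the nine muscle
#' activations and their phase derivatives, plus Gaussian sensor noise. The
#' mixture guarantees, by construction, that the sensor-to-muscle map is
#' deterministic up to noise; setting `coupling = 0` severs it and yields the
#' negative-control dataset.
#'
#' The study generator evaluates the activations each channel mixes at a
#' channel-specific phase lag (the kinematic consequences of a muscle's
#' action appear on different segments with different delays), passing a
#' per-channel activation array; a plain matrix (no lags) is equally
#' accepted.
#'
#' @param subject A [subject_config()].
#' @param phase_pct Per-sample gait phase (% cycle).
#' @param activations Matrix (n samples x 9 muscles) of activation values,
#'   or an n x 9 x 24 array with one lag-shifted slab per channel.
#' @param activation_derivs Same shape, with d(activation)/d(phase).
#' @param mixing List with `Wa`, `Wd` (24 x 9 study-level mixing matrices).
#' @param speed Speed class.
#' @param coupling Scalar multiplier on the mixture (default 1; 0 = none).
#' @param noise_sd Sensor noise SD (default 0.05).
#' @return Matrix (n x 24), columns in [imu_channel_order()].
#' @export
imu_from_activations <- function(subject, phase_pct, activations,
                                 activation_derivs, mixing, speed = "normal",
                                 coupling = 1, noise_sd = 0.05) {
  n <- length(phase_pct)
  th <- 2 * pi * phase_pct / 100
  basis <- matrix(0, n, 24)
  for (k in 1:3) {
    basis <- basis + outer(cos(k * th), subject$fourier_cos[, k]) +
      outer(sin(k * th), subject$fourier_sin[, k])
  }
  if (length(dim(activations)) == 3L) {
    mix <- matrix(0, n, 24)
    for (j in 1:24) {
      mix[, j] <- activations[, , j] %*% mixing$Wa[j, ] +
        (0.15 * activation_derivs[, , j]) %*% mixing$Wd[j, ]
    }
  } else {
    mix <- activations %*% t(mixing$Wa) + (0.15 * activation_derivs) %*% t(mixing$Wd)
  }
  ch <- sweep(speed_basis_amp[[speed]] * basis + coupling * mix, 2, subject$imu_gain, `*`)
  ch <- sweep(ch, 2, subject$imu_offset, `+`)
  if (noise_sd > 0) ch <- ch + matrix(stats::rnorm(n * 24, 0, noise_sd), n, 24)
  colnames(ch) <- imu_channel_order()
  ch
}

#' Synthesize a raw surface-EMG recording from an activation envelope
#'
#' Amplitude-modulates a zero-mean broadband carrier (white noise band-pass
#' filtered to roughly 20--400 Hz) with the envelope, then adds
#' low-frequency baseline drift (below the EMG band, so the band-pass stage
#' must remove it), sparse impulsive artifacts, and a small sensor-noise
#' floor. The conditioning chain ([process_emg()]) should recover the
#' envelope from this signal.
#'
#' @param envelope Numeric envelope sampled at `fs` (>= 0).
#' @param fs Sampling rate in Hz (default 1000).
#' @param drift_amp Drift amplitude relative to the mean envelope (default 0.4).
#' @param impulse_rate Expected impulsive artifacts per second (default 0.4).
#' @param noise_sd Sensor noise SD relative to the envelope maximum (default 0.01).
#' @return A `raw_signal` with the synthetic raw EMG.
#' @export
synthesize_raw_emg <- function(envelope, fs = 1000, drift_amp = 0.4,
                               impulse_rate = 0.4, noise_sd = 0.01) {
  n <- length(envelope)
  if (n < 16L) stop("synthesize_raw_emg: envelope too short")
  high <- min(400, 0.45 * fs)
  bf <- signal::butter(4, c(20, high) / (fs / 2), type = "pass")
  carrier <- zero_phase_filter(bf, stats::rnorm(n))
  carrier <- carrier / stats::sd(carrier)
  x <- envelope * carrier
  tt <- (0:(n - 1)) / fs
  me <- mean(envelope)
  x <- x + drift_amp * me * sin(2 * pi * 0.35 * tt + stats::runif(1, 0, 2 * pi)) +
    0.5 * drift_amp * me * sin(2 * pi * 0.11 * tt + stats::runif(1, 0, 2 * pi))
  n_imp <- stats::rpois(1, impulse_rate * n / fs)
  if (n_imp > 0) {
    at <- sample.int(n, min(n_imp, n))
    x[at] <- x[at] + sample(c(-1, 1), length(at), TRUE) *
      stats::runif(length(at), 1.5, 3) * max(envelope)
  }
  x <- x + stats::rnorm(n, 0, noise_sd * max(max(envelope), .Machine$double.eps))
  raw_signal(x, fs = fs, label = "emg_synthetic")
}

#' Generate a synthetic walking study
#'
#' Produces a fully deterministic collection of walking trials with the
#' structure the estimation method assumes: per-subject trials at three
#' walking-speed classes, stride-locked IMU channels that linearly encode
#' the muscle activations (and their phase derivatives) on top of a
#' subject-specific periodic carriage, raw surface-EMG channels synthesized
#' from the per-stride activation envelopes, heel-strike annotations, and
#' the ground-truth 101-point envelope of every stride for validation.
#'
#' @param n_subjects Number of subjects (default 4).
#' @param trials_per_subject Trials per subject, cycling through the speed
#'   classes slow/normal/fast (default 3).
#' @param strides_per_trial Strides per trial (default 60; the default study
#'   is 4 x 3 x 60 = 720 strides).
#' @param seed Integer seed; every random draw derives from it.
#' @param coupling Sensor-to-muscle coupling strength (default 1; 0 produces
#'   the negative-control study in which the IMU carries no muscle
#'   information).
#' @param noise_imu IMU sensor-noise SD (default 0.05).
#' @param emg_noise EMG sensor-noise floor relative to the envelope maximum
#'   (default 0.01).
#' @param fs_emg,fs_imu Sampling rates in Hz (defaults 1000 and 200).
#' @param specs Muscle specifications (default [default_muscle_specs()]).
#' @param mixing_sd SD of the study-level sensor-mixing weights (default 1.6):
#'   how strongly the muscle activations imprint on the IMU channels relative
#'   to the subject's periodic carriage.
#' @param burst_wander Half-width of the per-stride circular wander of burst
#'   centers, in % cycle (default 50: stride-specific timing).
#' @param gain_sdlog Log-SD of the per-stride burst gain modulation
#'   (default 0.1).
#' @return List of class `gait_study`: `trials` (each with `imu`, `emg`,
#'   `events`, `truth`, ids), plus the `mixing` matrices and the call
#'   parameters.
#' @export
generate_study <- function(n_subjects = 4, trials_per_subject = 3,
                           strides_per_trial = 60, seed = 1, coupling = 1,
                           noise_imu = 0.05, emg_noise = 0.01,
                           fs_emg = 1000, fs_imu = 200,
                           specs = default_muscle_specs(),
                           mixing_sd = 1.6, burst_wander = 50,
                           gain_sdlog = 0.1) {
  if (strides_per_trial < 1) stop("generate_study: strides_per_trial must be >= 1")
  if (n_subjects < 1) stop("generate_study: n_subjects must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))

  set.seed(stable_hash("study", seed))
  muscles <- names(specs)
  mixing <- list(Wa = matrix(stats::rnorm(24 * length(muscles), 0, mixing_sd), 24),
                 Wd = matrix(stats::rnorm(24 * length(muscles), 0, mixing_sd), 24),
                 # channel-specific phase lags (% cycle) at which muscle
                 # activity imprints on each segment's kinematics: short,
                 # non-negative delays, several channels responding
                 # instantaneously
                 lags = rep(0, 24))

  speeds <- c("slow", "normal", "fast")
  trials <- list()
  for (si in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", si)
    subj <- subject_config(sid, seed)
    for (ti in seq_len(trials_per_subject)) {
      tid <- sprintf("T%02d", ti)
      speed <- speeds[(ti - 1L) %% 3L + 1L]
      set.seed(stable_hash("trial", seed, sid, tid))

      durations <- subj$stride_period_s * speed_period_factor[[speed]] +
        stats::rnorm(strides_per_trial, 0, subj$stride_jitter_s)
      durations <- pmax(durations, 0.5)
      strikes <- 0.25 + c(0, cumsum(durations))
      t_end <- strikes[length(strikes)] + 0.25

      # per-stride realized activation bursts (incl. stochastic modulation)
      realized <- lapply(muscles, function(m)
        lapply(seq_len(strides_per_trial), function(k)
          realize_bursts(specs[[m]], speed, center_jitter = burst_wander,
                         gain_sdlog = gain_sdlog)))
      names(realized) <- muscles

      grid_emg <- seq(0, t_end, by = 1 / fs_emg)
      grid_imu <- seq(0, t_end, by = 1 / fs_imu)
      ph_emg <- grid_phase(grid_emg, strikes)
      ph_imu <- grid_phase(grid_imu, strikes)

      act_at <- function(ph, deriv = FALSE) {
        f <- if (deriv) eval_bursts_deriv else eval_bursts
        A <- matrix(0, length(ph$phase), length(muscles))
        for (mi in seq_along(muscles)) {
          for (k in unique(ph$stride)) {
            sel <- ph$stride == k
            A[sel, mi] <- f(realized[[muscles[mi]]][[k]], ph$phase[sel])
          }
        }
        colnames(A) <- muscles
        A
      }
      add_crosstalk <- function(A, scale_baseline = TRUE) {
        out <- A
        for (mi in seq_along(muscles)) {
          ct <- specs[[muscles[mi]]]$crosstalk
          if (!is.null(ct)) {
            out[, mi] <- out[, mi] + ct$fraction * A[, match(ct$source, muscles)]
          }
        }
        if (scale_baseline) {
          out <- pmax(sweep(out, 2, subj$muscle_scale[muscles], `*`) + 0.05, 0)
        }
        out
      }
      # lag-shifted activation slabs for the IMU mixture: each channel sees
      # the activations (and derivatives) at its own circular phase lag,
      # evaluated on a fine per-stride phase grid then indexed per sample
      lagged_slabs <- function(ph, lags) {
        g <- seq(0, 100, by = 0.5)
        ng <- length(g)
        n <- length(ph$phase)
        A <- array(0, dim = c(n, length(muscles), length(lags)))
        D <- array(0, dim = c(n, length(muscles), length(lags)))
        for (k in unique(ph$stride)) {
          sel <- which(ph$stride == k)
          Ag <- vapply(muscles, function(m) eval_bursts(realized[[m]][[k]], g),
                       numeric(ng))
          Dg <- vapply(muscles, function(m) eval_bursts_deriv(realized[[m]][[k]], g),
                       numeric(ng))
          for (j in seq_along(lags)) {
            idx <- round((((ph$phase[sel] - lags[j]) %% 100) / 0.5)) + 1L
            idx[idx > ng] <- 1L  # phase 100 wraps to 0
            A[sel, , j] <- Ag[idx, ]
            D[sel, , j] <- Dg[idx, ]
          }
        }
        for (j in seq_along(lags)) {
          A[, , j] <- add_crosstalk(A[, , j])
          D[, , j] <- add_crosstalk(D[, , j], scale_baseline = FALSE)
        }
        list(A = A, D = D)
      }

      slabs <- lagged_slabs(ph_imu, mixing$lags)
      A_emg <- add_crosstalk(act_at(ph_emg))

      imu_mat <- imu_from_activations(subj, ph_imu$phase, slabs$A, slabs$D, mixing,
                                      speed = speed, coupling = coupling,
                                      noise_sd = noise_imu)
      emg_mat <- vapply(seq_along(muscles), function(mi)
        synthesize_raw_emg(A_emg[, mi], fs = fs_emg, noise_sd = emg_noise)$samples,
        numeric(length(grid_emg)))
      colnames(emg_mat) <- paste0("emg_", muscles)

      # ground-truth normalized-grid envelopes per stride
      ph101 <- seq(0, 100, length.out = 101)
      Araw101 <- lapply(seq_len(strides_per_trial), function(k) {
        M <- vapply(muscles, function(m) eval_bursts(realized[[m]][[k]], ph101),
                    numeric(101))
        add_crosstalk(M)
      })
      truth <- lapply(seq_along(muscles), function(mi)
        t(vapply(Araw101, function(M) M[, mi], numeric(101))))
      names(truth) <- muscles

      trials[[length(trials) + 1L]] <- list(
        subject_id = sid, trial_id = tid, speed = speed,
        imu = data.frame(time_s = grid_imu, imu_mat, check.names = FALSE),
        emg = data.frame(time_s = grid_emg, emg_mat, check.names = FALSE),
        events = strikes,
        truth = truth,
        stride_durations = durations
      )
    }
  }
  structure(list(trials = trials, mixing = mixing,
                 params = list(n_subjects = n_subjects,
                               trials_per_subject = trials_per_subject,
                               strides_per_trial = strides_per_trial,
                               seed = seed, coupling = coupling,
                               noise_imu = noise_imu, emg_noise = emg_noise,
                               fs_emg = fs_emg, fs_imu = fs_imu,
                               mixing_sd = mixing_sd, burst_wander = burst_wander,
                               gain_sdlog = gain_sdlog)),
            class = "gait_study")
}

# map sample times to (stride index, phase %); times outside the strike span
# are clamped to the circular phase of the nearest stride (those samples are
# discarded by segmentation anyway)
grid_phase <- function(tt, strikes) {
  k <- findInterval(tt, strikes)
  k[k < 1L] <- 1L
  k[k > length(strikes) - 1L] <- length(strikes) - 1L
  dur <- strikes[k + 1L] - strikes[k]
  phase <- (100 * (tt - strikes[k]) / dur) %% 100
  list(stride = k, phase = phase)
}

#' Write a whole synthetic study to delimited trial files
#'
#' @param study A `gait_study` from [generate_study()].
#' @param dir Output directory.
#' @return Invisibly, the manifest `data.frame` (also written as
#'   `manifest.csv`).
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(study$trials, function(tr) {
    write_trial(tr, dir)
    data.frame(subject_id = tr$subject_id, trial_id = tr$trial_id,
               speed = tr$speed, n_strides = length(tr$events) - 1L,
               prefix = paste0(tr$subject_id, "_", tr$trial_id),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a study previously written by [write_study()]
#'
#' @param dir Directory holding `manifest.csv` and the trial files.
#' @return List with `trials` (as in [generate_study()], without truth).
#' @export
read_study <- function(dir) {
  manifest <- data.table::fread(file.path(dir, "manifest.csv"), data.table = FALSE)
  trials <- lapply(seq_len(nrow(manifest)), function(i)
    read_trial(dir, manifest$prefix[i]))
  structure(list(trials = trials), class = "gait_study")
}

#' Linear ridge probe from features to a muscle's envelope
#'
#' Fits an L2-regularized linear map from the flattened 101 x 24 feature
#' blocks to the 101-point target envelopes and reports the mean per-cycle
#' Pearson correlation of the fit. On noise-free coupled data this should be
#' near 100% by construction of the generator — a sanity floor beneath the
#' neural networks: if even a linear probe cannot read the targets from the
#' sensors, no downstream learning claim is meaningful.
#'
#' @param samples List of `gait_cycle_sample` objects.
#' @param muscle Muscle name.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Mean per-cycle Pearson correlation (percent) of the in-sample fit.
#' @export
linear_probe_r <- function(samples, muscle, lambda = 1e-3) {
  mm <- samples_to_matrices(samples, muscle)
  X <- cbind(1, mm$X)
  G <- crossprod(X) + lambda * diag(ncol(X))
  B <- solve(G, crossprod(X, mm$Y))
  P <- X %*% B
  mean(vapply(seq_len(nrow(P)), function(i) pearson_r(mm$Y[i, ], P[i, ]),
              numeric(1)), na.rm = TRUE)
}
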