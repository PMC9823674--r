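# gaitemg

Estimation of lower-extremity muscle activity during walking from wearable
IMU signals, using feedforward and LSTM neural networks.

## The problem

Measuring muscle activity in gait normally requires surface EMG: several
carefully placed electrodes per muscle, crosstalk between neighbours, and a
wiring burden that can itself distort the walking pattern. Inertial
measurement units (IMUs) are small, cheap and wearable anywhere — but they
measure segment kinematics, not muscle activity. `gaitemg` implements a
learning-based surrogate: from the 3-axis accelerations and angular
velocities of four body-worn IMUs (trunk, thigh, shank, foot) it estimates
the normalized surface-EMG activation envelope of nine lower-extremity
muscles over each gait cycle.

The package contains the complete method, not just the models:

* **EMG conditioning** — zero-phase Butterworth band-pass (20–400 Hz),
  full-wave rectification, 8 Hz zero-phase low-pass linear envelope;
* **gait-cycle processing** — stride segmentation at heel strikes,
  time-normalization to 101 points (0–100 % of the gait cycle), median
  filtering, and invertible per-stride min–max normalization

  y_norm(i) = (y(i) − y_min) / (y_max − y_min),  i = 0, 1, …, 100;

* **estimators** — a feedforward network (input: the 101 × 24 feature block
  flattened) and an LSTM (input: the 101-step sequence of 24 channels),
  both with 4 × 256 hidden units by default, dropout between layers, `tanh`
  hidden / `sigmoid` output activations, MSE loss and Adam, written in
  C++ (no deep-learning framework required), trained one model per muscle
  with early stopping and bit-reproducible seeding;
* **evaluation** — per-cycle nRMSE (RMSE over the actual cycle's range),
  Pearson r, and signed timing (ΔTp) and relative amplitude (ΔEp) error of
  the peak muscle contraction, aggregated per muscle as mean ± SD;
* **reconstruction** — predicted cycles are denormalized with their stored
  parameters and stitched back into continuous time using the heel strikes;
* **a synthetic gait-data generator** — stride-locked IMU channels that
  linearly encode the muscle activations, raw surface-EMG synthesized from
  per-stride activation envelopes, heel-strike annotations and per-subject
  variability — so the full pipeline trains and validates offline, with
  ground truth available for every stride.

See `vignettes/methods.Rmd` for the model, the processing chain, what the
generator does and does not emulate, and all numerical choices.

## Worked example

```r
library(gaitemg)

# a small synthetic study: 3 subjects x 2 trials x 30 strides = 180 cycles
study   <- generate_study(n_subjects = 3, trials_per_subject = 2,
                          strides_per_trial = 30, seed = 42)
samples <- build_study_samples(study)          # condition, segment, normalize
split   <- split_dataset(samples, seed = 42, unseen_subject = "S03")

cfg <- model_config("lstm", hidden_layers = 2, hidden_units = 64,
                    dropout_rate = 0.1, learning_rate = 2e-3, batch_size = 64,
                    max_epochs = 60, early_stop_patience = 10, seed = 42)
est <- train_estimator(build_estimator(cfg), split, "gastrocnemius")

mm <- samples_to_matrices(split$test, "gastrocnemius")
evaluate_group(mm$Y, predict(est, mm), muscle = "gastrocnemius")
```

which trains in a few seconds on one CPU and prints:

```
         muscle group n_cycles n_excluded nrmse_mean nrmse_sd r_mean  r_sd
1 gastrocnemius  test        6          0      18.55    5.104  80.26 18.44
  delta_tp_abs_mean delta_tp_abs_sd delta_tp_signed_mean delta_tp_signed_sd
1                 6           3.742                   -6              3.742
  delta_ep_mean delta_ep_sd
1         24.71       7.163
```

one row per muscle and group: mean ± SD of nRMSE (%), Pearson r (%), peak
timing error |ΔTp| (% of gait cycle, with the signed aggregate alongside)
and peak amplitude error ΔEp (%), plus the number of cycles excluded
because a metric was undefined for them (e.g. a constant actual cycle). At
this toy size (96 training cycles) the fit is rough; the shipped acceptance
script trains on the full default study of 720 cycles, where held-out r
reaches the low 90s.

An end-to-end run — simulate, preprocess, split, train both architectures
for every muscle, predict, evaluate, reconstruct — with artifacts on disk:

```r
run_pipeline(default_config(), "my_run")   # full size: slow on one CPU
```

or from a shell, stage by stage:

```sh
Rscript inst/cli/gaitemg.R simulate   --run-dir my_run
Rscript inst/cli/gaitemg.R preprocess --run-dir my_run
Rscript inst/cli/gaitemg.R train      --run-dir my_run --muscle soleus --arch lstm
Rscript inst/cli/gaitemg.R run-all    --run-dir my_run
```

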