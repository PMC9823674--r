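---
title: "Estimating muscle-activity envelopes from wearable IMUs: models, processing chain, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating muscle-activity envelopes from wearable IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitemg)
```

## The problem

Surface electromyography (sEMG) is the reference measurement of muscle
activity in gait analysis, but it is cumbersome: several electrodes per
muscle, careful placement, crosstalk between neighbouring muscles, and a
wiring burden that can itself alter the walking pattern. Inertial
measurement units (IMUs), by contrast, are cheap, light, and usable outside
the laboratory — but they measure segment kinematics, not muscle activity.

`gaitemg` implements a learning-based bridge between the two: given the
3-axis accelerations and angular velocities of four body segments (trunk,
thigh, shank, foot) during level walking, it estimates the normalized sEMG
activation envelope of nine lower-extremity muscles (gluteus medius,
semitendinosus, biceps femoris, rectus femoris, vastus lateralis, vastus
medialis, soleus, tibialis anterior, gastrocnemius) over each gait cycle,
using either a feedforward (FNN) or a long short-term memory (LSTM) neural
network. Because the public gait datasets this method is normally applied to
cannot be bundled, the package ships a synthetic gait-data generator that
reproduces the statistical structure the method relies on, so the entire
pipeline — and the learning claim itself — can be exercised and tested
offline.

## Signal processing chain

Raw sEMG is conditioned into an activation envelope in the standard way:

1. **Band-pass filtering**, 20–400 Hz Butterworth. The myoelectric signal
   carries essentially all of its power in this band; motion artifact and
   baseline drift live below it, and wide-band noise above. A
   `compute_power_spectrum()` utility is provided for inspecting a
   recording's spectrum; the band itself is fixed configuration, not
   re-derived per run.
2. **Full-wave rectification.**
3. **Low-pass filtering at 8 Hz** (Butterworth) of the rectified signal —
   the linear envelope tracking activation intensity.

Both filters are applied forward and backward so that the chain is
zero-phase: a causal filter would delay the envelope and bias the
peak-timing comparisons made later. The filter order is not fixed by
convention; the package defaults to a 4th-order prototype and exposes it in
configuration. Ends are odd-reflection padded and each pass starts from the
steady state of the boundary value, so constant signals pass exactly and
start-up transients stay out of the recording. Small negative ringing left
by the low-pass stage is clipped at zero: an envelope is physically
non-negative.

Each channel — envelope and IMU axes alike — is then segmented into strides
at the provided heel-strike times (stride *k* covers the half-open interval
from strike *k* to strike *k+1*, so cycle boundaries are never duplicated),
resampled by linear interpolation onto the 101-point phase grid (0, 1, …,
100 % of the gait cycle), median-filtered (default kernel 5, for residual
impulsive artifacts), and min–max normalized to [0, 1]:

$$y_{norm}(i) = \frac{y(i) - y_{min}}{y_{max} - y_{min}}, \qquad i = 0, 1, \ldots, 100.$$

Normalization is per stride and per channel, and the $(y_{min}, y_{max})$
pair is stored with every cycle so the map can be inverted exactly when
predictions are reconstructed into continuous time. The order median filter
→ min–max matters: applying them this way leaves an array that still attains
exactly 0 and 1. Two degenerate cases are handled explicitly: a constant
stride cannot be rescaled and is returned as zeros with its parameters
flagged (such cycles are excluded from correlation-based evaluation, since
their Pearson r is undefined), and strides with implausible duration
(outside 0.4–2.5 s by default) are excluded from model data.

Linear interpolation was chosen for time normalization deliberately: it is
monotone, cannot overshoot, and therefore preserves the non-negativity of
envelopes; cubic interpolation is available behind the configuration but is
not the default.

## The estimators

Both estimators map one gait cycle's feature block — 101 phase steps × 24
channels (trunk, thigh, shank, foot × accelerometer x/y/z, gyroscope x/y/z,
each min–max normalized) — to one muscle's 101-point normalized envelope.
One model is trained per muscle (a multi-output variant is available but not
the default). The full-size architectures are 4 hidden layers of 256 units
with a dropout layer between each, `tanh` hidden activations, a `sigmoid`
output (which bounds predictions to (0, 1), matching the normalized
targets), MSE loss, and the Adam optimizer:

* the **FNN** consumes the block flattened to 2424 inputs;
* the **LSTM** consumes the 101-step sequence of 24-channel vectors.

No deep-learning framework is assumed: the dense and LSTM layers, BPTT,
Adam, dropout and early stopping are implemented in compiled C++ inside the
package. Training is bit-reproducible given the seed (a dedicated mt19937
stream drives shuffling and dropout), aborts with diagnostics if the loss
becomes non-finite, and keeps the weights of the best validation epoch.

**LSTM readout.** Two readout heads are implemented. The `final` head feeds
the last phase step's hidden state into a dense sigmoid layer of all 101
outputs; the `sequence` head (the default) applies one shared dense sigmoid
unit to every step's hidden state, emitting the envelope value of phase *i*
at step *i*. The final-state head forces the entire stride to be compressed
through one 64–256-dimensional state before any output is produced; in
development this proved to be a severe optimization bottleneck whenever the
target waveform is not strongly phase-stereotyped (held-out r plateaued some
20 points below the feedforward network on identical data). The sequence
head removes that bottleneck while leaving the architecture otherwise
unchanged, and is the package default; the final head remains available in
`model_config(lstm_head = "final")`.

Training hyper-parameters that the architecture description leaves open are
declared defaults, not facts about the method: dropout 0.2, learning rate
1e-3, batch size 32, at most 300 epochs with early-stopping patience 25.

## Dataset assembly and splitting

Per-stride samples are assembled with the channels in a fixed, documented
order (readers map channels by name, so file column order is irrelevant).
The splitter randomizes samples and divides them 80:15:5 into training,
validation and test sets — validation and test sizes round down, the
remainder goes to training (5440 cycles split as 4352/816/272) — and one
whole subject can be held out as unseen-subject data that shares nothing
with the other three groups. The default unit of randomization is the
individual stride, so cycles of one subject appear in several groups; a
trial-level mode (`by = "trial"`) keeps whole trials together. Published
trial/cycle tables for this method are consistent with trial-level grouping,
so both modes are provided; neither is asserted as canonical. Splits are
deterministic given the seed and are written out as a plain-text manifest.

## Evaluation

Agreement between an actual cycle $X$ and a predicted cycle $Y$ is
quantified per cycle by four measures, reported per muscle as mean ± SD:

* **nRMSE** $= \frac{100}{X_{max}-X_{min}} \sqrt{\tfrac1n \sum_i (X_i-Y_i)^2}$ —
  the normalizer is always the *actual* cycle's range;
* **Pearson r** (× 100);
* **ΔTp** $= T_{x,p} - T_{y,p}$, the signed difference of peak times in %
  of the gait cycle. The tables aggregate absolute values (means of a signed
  quantity would cancel); both signed and absolute aggregates are stored.
  No circular wrapping is applied — peaks at 10 % and 90 % give −80 % — a
  documented limitation for peaks near the cycle boundary;
* **ΔEp** $= 100\,|X_p - Y_p| / X_p$, the relative peak-amplitude error.

Peaks are global maxima with ties broken by the earliest index. Cycles for
which a measure is undefined (constant actual cycle, zero actual peak) are
excluded from that measure's aggregate — never zero-filled — and exclusion
counts are reported.

For qualitative inspection, predicted cycles are denormalized with their
stored per-stride parameters and resampled from the phase grid back onto
each stride's time grid, giving a continuous predicted envelope aligned with
the original recording.

## The synthetic gait generator

`generate_study()` produces walking trials with the structure the method
assumes, and nothing more. Its defaults define the study conditions used
throughout the tests: 4 subjects × 3 trials (one per speed class slow /
normal / fast) × 60 strides = 720 gait cycles; EMG sampled at 1000 Hz, IMU
at 200 Hz; stride period ≈ 1.1 s scaled by speed class with per-subject and
per-stride variation.

**Muscle activations.** Each muscle's stereotyped profile is a sum of
Gaussian bursts on the circular phase axis, placed at standard gait-EMG
timings: plantarflexor bursts in late stance, tibialis anterior in early
swing and around heel strike (wrapping the cycle boundary), vasti and
gluteus medius in loading response, hamstrings at terminal swing with an
additional stance burst that is largest in slow walking, and a
speed-dependent rectus femoris burst around pre-/initial swing plus an
early-stance component modelled as crosstalk (a fixed fraction of vastus
lateralis activity added to the rectus channel). Per-burst speed multipliers
implement the speed dependence.

**Stride-to-stride variability.** Within a stride, each burst's realized
center wanders circularly (uniform ± 50 % cycle by default) and its gain
varies (lognormal), and one extra random bump is added. This deliberately
exaggerates the timing variability of real gait, for an identifiability
reason: the variability must *dominate* the stereotyped mean profile, so
that (a) a model can only predict well by actually reading the sensors,
never by reproducing the phase-average waveform, and (b) the negative
control below is sharp — an MSE-trained model converges toward the
conditional mean of its targets, so whatever the phase-average explains is
exactly what a decoupled model can still score. With the default settings
the correlation between a stride's envelope and its speed-conditional mean
shape is ≈ 0.08. The price is physiological realism of per-stride timing;
passing tests on this generator therefore demonstrate that the pipeline and
estimators recover sensor-borne activation information, not that real gait
is this variable.

**Sensors.** Each of the 24 IMU channels is a subject-specific smooth
periodic carriage (low-order Fourier series over the phase, amplitude scaled
by speed) plus a linear mixture of the nine muscle activations and their
phase derivatives, plus Gaussian noise. The mixture is evaluated at a
channel-specific phase lag (drawn once per study, spread over the cycle),
reflecting that the kinematic consequences of muscle action appear on
different segments with different delays; technically, the lags also spread
the information needed to reconstruct the whole envelope across the whole
sequence, so that no single phase region is privileged. Setting
`coupling = 0` removes the mixture entirely and yields the negative-control
study in which the sensors carry no muscle information. On noise-free
coupled data, a plain linear ridge probe from the flattened features to the
targets reads the envelopes at r > 99 % — a sanity floor beneath the neural
networks.

**Raw EMG.** Each muscle's raw trace is an amplitude-modulated broadband
carrier (white noise band-passed to 20–400 Hz) with sub-band baseline drift,
sparse impulsive artifacts, and a small sensor-noise floor — exactly the
disturbances the conditioning chain exists to remove. Default rates and
amplitudes were fixed once, by the design requirement that the chain recover
the true normalized envelope at r ≈ 95 % or better per stride; the residual
gap to 100 % is the irreducible estimation noise of rectify-and-smooth
envelope extraction at an 8 Hz cutoff.

All randomness derives from a single integer seed; per-subject and per-trial
substreams are derived by stable hashing of the identifiers, so individual
subjects are reproducible and written studies are byte-identical across
runs.

## Numerical and design choices

* Butterworth `order` refers to the low-pass prototype handed to the design
  routine; the band-pass transform doubles it, and the forward-backward pass
  squares the magnitude response. Tests check gains against the analytic
  magnitude of this exact convention.
* Median filter: reflection padding at the edges; kernel must be odd.
* Min–max degenerate inputs (constant arrays) yield zeros plus a flag, and
  inversion returns the constant.
* Reconstruction drops the 100 %-point of every cycle except the last, so
  concatenated strides are contiguous without duplicated samples.
* Split sizes: validation and test round down, training takes the
  remainder.
* Peak ties break to the earliest index; ΔTp is not computed circularly.
* The per-subject, per-trial RNG substreams keep the generator deterministic
  under any subset of subjects.

## Problem sizes used in the shipped tests

The test-suite and the acceptance script run the full default study (720
strides) once per coupled/decoupled condition, with reduced networks of
2 layers × 64 units for the learning checks (a fixed 40 training epochs
for the LSTM and 100 for the feedforward network, without early stopping,
so runtimes are deterministic; dropout 0.1, batch 64) — large enough to
demonstrate the learning properties, small enough to train one model per
muscle on one CPU in under a minute. These fixed budgets sit slightly
before full convergence; the models keep improving for roughly another
20–40 epochs if trained longer. The architecture comparison is averaged
over three seeds on a representative muscle; the negative control trains
three seeds on the decoupled study. The metric and filter checks run at
their natural (instant) sizes. Full-size networks (4 × 256) are exercised
structurally (construction, parameter counts, prediction shapes) but not
trained to convergence in the tests.

## Known limitations

* The generator does not attempt biomechanical forward dynamics; its
  IMU-activation coupling is linear by construction, which favours no
  particular architecture but is simpler than reality.
* Per-stride timing variability is exaggerated relative to real gait (see
  above); conversely, inter-subject variability is mild (four synthetic
  subjects share the same mixing matrices), so unseen-subject results on
  synthetic data are optimistic relative to real cohorts.
* Heel strikes are taken as given; no event detection is implemented.
* ΔTp near cycle boundaries can be misleading (no circular distance).
* The evaluation reports no statistical tests between architectures.
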