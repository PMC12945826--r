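---
title: "Respiratory motion modelling with respmotion: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Respiratory motion modelling with respmotion: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiotherapy of thoracic and upper-abdominal tumors is degraded by
respiratory motion: the target moves by millimetres to centimetres over a
breathing cycle, while the delivery chain (imaging, multileaf-collimator
repositioning, beam gating) reacts with a latency of roughly 50--500 ms.
A motion-management model therefore has four linked jobs:

1. **Motion-range classification** — bin each record's peak-to-trough
   amplitude (the *estimated range of motion*, EROM) into four clinically
   motivated classes: 0--4 mm, 4--6 mm, 6--8 mm and ≥ 8 mm, reported with
   representative values 3.99 / 5.99 / 7.99 / 10.00 mm.
2. **Latency compensation** — predict the future target position 1--10
   samples ahead (50--500 ms at 20 Hz) so the beam can lead the motion.
3. **Signal reconstruction** — compress each observation window to a
   low-dimensional latent code and reconstruct a physiologically coherent
   breathing curve from it, which regularizes the representation and
   exposes inconsistent segments.
4. **Excessive-motion detection** — flag amplitudes at or above 9 mm,
   which exceed common planning margins and gating tolerances.

`respmotion` implements this pipeline end to end: a synthetic-signal
generator that stands in for clinical surrogate data, wavelet denoising,
windowing, a hybrid dilated-convolution / bidirectional-LSTM /
autoencoder network trained jointly on all four tasks, and the complete
evaluation protocol.

## The synthetic generator

Clinical respiratory surrogate traces cannot be redistributed, so the
package ships a generator whose output is statistically similar to
denoised surrogate data and fully labelled by construction. The SI-axis
waveform follows the standard respiratory motion model

$$ z(t) = b\,\mathrm{env}(t)\left(\tfrac{1}{2} - \cos^{2n}(\theta(t))\right), $$

a cosine-power trace with a sharp quadratic trough at end-exhale and a
flattened inhale plateau (`waveform_exponent` n = 2, i.e. cos⁴, by
default). The phase advances piecewise-linearly through per-cycle periods
$\tau_k = \bar\tau (1 + c_v \varepsilon_k)$; because the waveform has zero
slope at its troughs, period changes join smoothly. The initial phase is
drawn uniformly on the sample grid, so that in the fully regular case
peaks and troughs fall exactly on samples and the per-cycle EROM equals
the target amplitude to machine precision — a property the tests rely on.

Irregularity enters through five channels, each with a default chosen to
represent moderately irregular free breathing:

| parameter | default | meaning |
|---|---|---|
| `period_mean_s`, `period_sd_s` | 4.0, 0.5 s | between-record breathing period |
| `am_depth`, `am_period_s` | 0.1, 25 s | slow sinusoidal waxing–waning of amplitude |
| `jitter_cv` | 0.05 | per-cycle period jitter (CV) |
| `drift_amplitude_mm`, `drift_period_s` | 0.3 mm, 60 s | baseline wander |
| `artifact_rate` | 0.2 / 120 s | cough-like Gaussian bumps (2 mm, 0.3 s) |
| `noise_sd_mm` | 0.05 mm | additive white measurement noise |

AP and LR are scaled copies of the SI axis (ratios 0.4 and 0.3) with
independent noise. The sampling rate default of 20 Hz makes every stated
latency bin a whole number of samples (50 ms = 1 sample, 500 ms = 10).
Records are 120 s long, one PET/CT bed position.

**Labels are derived from the generated clean trace, not from the
target**: `segment_cycles()` finds end-exhale troughs on the clean SI
axis, per-cycle EROM is the within-cycle max − min per axis, and the
label's dominant amplitude is the maximum over axes of the mean per-cycle
EROM. This keeps labels exactly reproducible by an independent
trough-scanning oracle, which the tests exercise.

`simulate_breathing()` organises records into synthetic patients (4
segments each) that share one base amplitude, so patient-wise splits are
meaningful and subject leakage is impossible. Per-class base amplitudes
are drawn uniformly within each class bin but with a small interior
margin (class 1 on [0.5, 3.75] mm, class 2 [4.10, 5.90], class 3
[6.10, 7.75], class 4 [8.10, 15.0] — the upper class-4 bound reflecting
free-breathing lung-tumor motion of 10--15 mm). The margin exists because
the realized, trace-derived EROM differs from the target by up to a few
tenths of a millimetre (envelope mean, drift, artifacts); without it a
record sampled at 3.99 mm could legitimately realize 4.05 mm and change
class, breaking the contract that the generated mixture matches the
requested one. Sub-0.5 mm amplitudes are excluded as below surrogate
measurement resolution.

**What the generator does not emulate**: inter-axis hysteresis (AP/LR
are exact scalings of SI), breath holds and apneas, the HU-derived
surrogate's imaging-noise structure, inter-fraction variability, and any
physical calibration of surrogate units to tumor millimetres. Results on
this benchmark therefore demonstrate that the pipeline's machinery works
and recovers known structure — not clinical performance.

## Denoising

`dwt_denoise()` applies a per-axis multilevel discrete wavelet transform
(db4, level 4 by default — the conventional family/depth for respiratory
and other biomedical signals), soft-thresholds all detail coefficients at
the universal threshold $\sigma\sqrt{2\ln N}$ with the noise scale
estimated from the finest detail band as
$\sigma = \mathrm{median}(|d_1|)/0.6745$, and inverts the transform. The
approximation band, which carries the breathing pattern (fundamental
0.25 Hz and its low harmonics at 20 Hz sampling), is never touched.

The transform uses the *periodized* orthogonal filter bank: analysis is
the transpose of synthesis, so reconstruction without thresholding is
exact to numerical precision at any length (signals not divisible by
$2^L$ are reflection-extended and truncated after inversion). A symmetric
boundary was considered and rejected because decimated symmetric
extension does not reconstruct perfectly, and exact perfect
reconstruction is both a stated invariant of the transform and the
property the tests verify. No installed R package provides a DWT, so the
filter bank is implemented in the package; db1/db2 are included for
testing alongside the db4 default.

## Cycle segmentation

Cycles are delimited trough-to-trough (end-exhale anchored, matching the
most common gating convention). Troughs are strict local minima that
survive two filters: prominence of at least 10% of the record's SI
amplitude range (the prominence of a candidate being the smaller of the
highest excursions towards its neighbouring candidates), and a minimum
separation of half the nominal period, enforced greedily keeping the
deeper of any too-close pair. The nominal period comes from the
generator's metadata when available and otherwise from an
autocorrelation estimate. Records with fewer than two qualifying troughs
yield an empty cycle table rather than an error — a 3-s record is a
degenerate input, not a bug.

## Normalization

The pipeline maps displacements to [0, 1] with one *fixed* affine
transform shared by all records: −10 mm ↦ 0, +10 mm ↦ 1 (signals are
generated centred, and ±10 mm spans the class-4 range plus drift and
artifacts). A per-record min-max normalization is also provided
(`normalize_signal(method = "minmax")`, with degenerate constant axes
mapped to 0.5 and flagged), but it is *not* used by the windowing
pipeline: rescaling every record to unit range erases absolute amplitude,
and with it the very quantity the motion-range classifier must recover —
two noise-free records of 2 mm and 10 mm amplitude become
indistinguishable. Both transforms are stored with the data and are
exactly invertible, and prediction targets share the input's transform so
errors are commensurable across heads. All reported errors are in these
normalized units (1 unit = 20 mm); the underlying surrogate signals have
no validated physical calibration, which is also why the evaluation
stays in normalized amplitude.

## Windowing

`make_windows()` slides a 120-sample (6 s, ~1.5 breathing cycles) window
over the denoised, normalized trace. Each window carries the record's
class and excessive flag, the *clean-trace* future position at horizons
1, 3, 6 and 10 samples (labelled with the latency bins 40--50, 100--150,
200--300 and 400--500 ms) for each axis, and the clean window itself as
the reconstruction target. Targets come from the clean trace because the
evaluation is a parameter-recovery exercise: the reference positions the
errors are measured against are themselves smoothed surrogates, so
predicting the clean component is the well-posed task. At stride 1 the
window count is $N - W - h_{\max} + 1$; the default benchmark uses stride
240 (12 s), giving 9 windows per record — enough phase diversity per
record while keeping a full run at desk scale.

## The network

The architecture, sizes in parentheses all configurable via
`motion_net_config()`:

* **Dilated causal convolutions** (4 layers, 32 channels, kernel 3,
  dilations 1/2/4/8), each followed by layer normalization over channels,
  ReLU, and spatial (channel-wise) dropout (rate 0.2). Causal left
  zero-padding preserves length and temporal order. The stack's receptive
  field, $1 + (k-1)\sum d = 31$ samples ≈ 1.5 s, spans half a breathing
  cycle — the smallest stack that can see a full exhale-to-inhale limb.
* **Bidirectional LSTM** (one layer, 64 hidden units per direction) over
  the conv features; the trunk summary concatenates the forward stream's
  final state and the backward stream's final state (128 features).
* **Autoencoder bottleneck**: a tanh encoder maps the trunk summary to a
  16-dimensional latent code z; the decoder (tanh hidden layer of 128,
  then affine) reconstructs the flattened 120 × 3 clean window. A single
  affine decoder was tried conceptually and rejected: a rank-16 linear
  map cannot represent phase-shifted quasi-periodic windows at useful
  fidelity, so the decoder carries one hidden layer.
* **Heads**: all heads read the trunk summary *augmented with scaled
  per-axis window amplitude statistics* (ten times the window range and
  the centred mean level). The augmentation exists because per-position
  layer normalization makes the convolutional features largely
  scale-invariant — with zero biases exactly so — which would hide
  absolute amplitude, the very quantity the motion-range and
  excessive-motion heads must recover; the ×10 scaling puts
  class-relevant differences at O(1) so the required head weights are
  reachable within a short training budget. The regression head
  additionally sees the window's last observed sample and its local
  slopes, and its output is a *residual added to a per-horizon
  linear-extrapolation base* (last sample plus horizon times a smoothed
  4-sample slope). Persistence and linear extrapolation are thereby
  exactly representable as the zero-residual case, so the network learns
  corrections (curvature, phase) rather than absolute positions; without
  this, a linear readout of the recurrent summary cannot even match
  persistence at the shortest horizon within 20 epochs, because Adam's
  per-parameter step bounds the reachable weight magnitude. For the same
  reason, the head weight rows acting on the augmented statistics start
  at zero: the initial forward pass is driven purely by the recurrent
  trunk, and the statistics enter only as training pulls them in.

Training minimizes the composite loss

$$ L = \lambda_{cls}\,\mathrm{CE} + \lambda_{reg}\,\mathrm{MSE} +
      \lambda_{rec}\,\mathrm{MAE} + \lambda_{exc}\,\mathrm{BCE}, $$

with default weights (1, 100, 20, 1). The weights are deliberately not
equal: with all signals in [0, 1], the cross-entropy term is O(1) while
the squared position error is O(10⁻⁴), so under equal weights the shared
trunk's gradient is dominated by classification and the regression and
reconstruction heads underfit badly (in early experiments the regression
head then failed to beat a persistence baseline). The chosen weights
bring the four terms' gradient contributions to a comparable scale;
reconstruction keeps the mean *absolute* error as its criterion, which is
robust to the occasional artifact bump.

Optimization is minibatch Adam (learning rate 10⁻³, batch 64, at most 20
epochs) with early stopping on the validation composite loss (patience
5); the parameters of the best validation epoch are restored. All
randomness — Glorot initialization, shuffling, dropout — derives from the
configuration seed, and the engine (hand-written in RcppArmadillo, since
no deep-learning framework is available to R here) is single-threaded
double precision, so identical data, configuration and seed reproduce
training bit for bit. Gradients of every layer are verified against
central finite differences in the test suite. A NaN training loss aborts
with a diagnostic rather than continuing silently.

## Evaluation protocol

`latency_sweep()` computes, on held-out windows: the 4 × 4 confusion
matrix (argmax prediction, ties broken toward the lower class — the
conservative motion estimate), accuracy, per-class precision/recall/F1
(0/0 defined as 0 and flagged), one-vs-rest AUC per class via the
Mann–Whitney rank statistic with tie averaging (equivalent to
trapezoidal ROC integration, and cross-checked against an all-pairs
oracle in the tests), per-axis and axis-averaged RMSE of the predicted
future position at every latency bin against the clean trace, the
reconstruction MAE, and precision/recall of the excessive flag at
probability 0.5. The reconstruction target does not depend on the
horizon, so the per-bin reconstruction MAE column repeats one value; it
is reported per bin to keep the table shape of the protocol. Reports can
retain per-window residuals, and the tests verify that every aggregate
is exactly recomputable from them. Following the protocol, no confidence
intervals are attached; a deliberate omission, not an oversight.

Two reference predictors give the latency sweep a runnable comparison:
persistence (future = last observed value) and two-point linear
extrapolation. On a stationary sinusoid of angular frequency ω the
persistence error has the closed form $\sqrt{1 - \cos\omega h}$, which
the acceptance tests use as an exactness check.

## The default benchmark

`run_benchmark()` is the package's reference experiment and what
`scripts/acceptance.R` reruns: 800 simulated records (200 patients,
balanced classes), denoised, windowed at stride 240, split patient-wise
80/20 with 10% of the training patients reserved for early stopping,
trained with the default configuration, and evaluated on the held-out
patients (1600 windows). The problem size is a deliberate desk-scale
choice: it completes on a single CPU in minutes while leaving enough
test windows for stable rank statistics. All quantities quoted in the
README are produced by running it.

## Known limitations

* Synthetic axes are perfectly correlated scalings, so per-axis errors
  differ only by the axis ratio; real AP/LR traces carry independent
  structure and hysteresis.
* Window-level classification inherits an irreducible ambiguity near the
  class edges: amplitudes are drawn across each bin and the slow
  amplitude modulation makes a 6-s window's local amplitude a ±7%
  estimate of the record's mean EROM, so records within that band of an
  edge cannot be classified perfectly from one window. Record-level
  aggregation (majority vote over windows) is available in
  `predict()` output via the per-window table if a user wants it.
* The excessive-motion flag shares this edge ambiguity around 9 mm.
* No GPU path and no hyperparameter search; the configuration family is
  fixed and documented, and all sizes are arguments.
* Surrogate units are not calibrated to physical millimetres of tumor
  motion; dosimetric consequences are out of scope.
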