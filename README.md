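# respmotion

Respiratory-motion management tools for image-guided radiotherapy
research: simulation of labelled multi-axis breathing surrogate signals,
wavelet denoising, and a hybrid dilated-convolution / bidirectional-LSTM
/ autoencoder network that jointly

1. classifies each record's motion range into four amplitude bins
   (0–4, 4–6, 6–8, ≥ 8 mm, reported as 3.99 / 5.99 / 7.99 / 10.00 mm),
2. predicts future tumor position across 50–500 ms latency horizons
   (the reaction delay of imaging, MLC repositioning and gating),
3. reconstructs physiologically coherent breathing curves through a
   low-dimensional autoencoder bottleneck, and
4. flags excessive motion (≥ 9 mm, beyond common planning margins).

It is aimed at researchers prototyping latency-compensation and motion
classification pipelines who need a fully reproducible, labelled stand-in
for clinical surrogate data, plus the complete evaluation protocol
(confusion matrices, per-class precision/recall/F1 and one-vs-rest AUC,
per-axis and per-latency RMSE, reconstruction MAE, PSNR utility,
persistence and linear-extrapolation baselines).

## The model in brief

Signals are quasi-periodic cosine-power traces
`z(t) = b · env(t) · (1/2 − cos²ⁿ(θ(t)))` on the superior–inferior axis
(AP and LR are scaled copies), with amplitude modulation, per-cycle
period jitter, baseline drift, cough-like transients and white noise.
Records are denoised per axis by a level-4 db4 discrete wavelet
transform with soft universal thresholding (`σ√(2 ln N)`,
`σ = median(|d₁|)/0.6745`), windowed (120 samples at 20 Hz), and mapped
to [0, 1] by one fixed affine transform shared across records.

The network applies dilated causal convolutions (kernel 3, dilations
1/2/4/8, layer norm + ReLU + spatial dropout), a BiLSTM (64 hidden units
per direction) whose two final states summarize the window, an
autoencoder bottleneck `z = f(Wu + b)` (16 dimensions) with a generative
decoder, and four task heads trained jointly with the composite loss

```
L = λ_cls·CE + λ_reg·MSE + λ_rec·MAE + λ_exc·BCE .
```

Future positions are parameterized as residuals on a per-horizon
linear-extrapolation base, so trivial predictors are nested in the model
class. Training (minibatch Adam, early stopping on a patient-wise
validation split) is bit-reproducible from one seed. The engine is
hand-written RcppArmadillo with analytically derived gradients, verified
against finite differences in the test suite.

## Worked example

```r
library(respmotion)

rec <- generate_signal(6.5, generator_config(), seed = 11)
rec$signal
#> <resp_signal 'sig_seed11': 2400 samples @ 20 Hz (120.0 s), with clean trace>

as.data.frame(rec$label)
#>   erom_si_mm erom_ap_mm erom_lr_mm dominant_amplitude_mm motion_class
#> 1      6.589      2.636      1.977                 6.589            3
#>   representative_value_mm excessive
#> 1                    7.99     FALSE
```

The record was asked for a 6.5 mm SI amplitude; the label is *measured
back* from the generated clean trace (mean per-cycle peak-to-trough,
dominant axis), lands at 6.59 mm and therefore in class 3 (6–8 mm), not
excessive. Denoise and segment breathing cycles:

```r
den <- dwt_denoise(rec$signal)
cyc <- segment_cycles(den)
head(cyc, 3)
#>   cycle start_idx end_idx start_time_s end_time_s period_s erom_si_mm ...
#> 1     1        18      98         0.85       4.85      4.0       6.08
#> 2     2        98     170         4.85       8.45      3.6       6.05
#> 3     3       170     240         8.45      12.0       3.5       6.51
nrow(cyc)
#> [1] 32
```

Thirty-two trough-to-trough cycles, per-cycle periods wobbling around
the record's 3.7 s base period, per-cycle EROM around the 6.5 mm target —
exactly the structure the classifier and predictor must recover.
`autoplot(rec$signal)` draws the three axes; the full pipeline is

```r
ds      <- simulate_breathing(40, seed = 1)             # labelled records
windows <- prepare_windows(ds, window_spec(stride = 240))
split   <- split_patients(windows, seed = 2)
fit     <- fit_motion_net(subset_windows(windows, split$train),
                          motion_net_config(),
                          val_windows = subset_windows(windows, split$val))
report  <- latency_sweep(fit, subset_windows(windows, split$test))
report; tidy(report); autoplot(report)
```

`run_benchmark()` wraps these steps into the package's reference
experiment (800 records, balanced classes, patient-wise 80/20 split).
A command-line surface (`simulate`, `preprocess`, `train`, `evaluate`,
`predict`, `report`) is available through `respmotion_cli()` and the
`inst/scripts/respmotion` wrapper.

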