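test_that("the wavelet transform reconstructs perfectly at any length", {
  withr::with_seed(11, {
    for (n in c(256, 1000, 2400)) {
      x <- stats::rnorm(n)
      d <- dwt_decompose(x, "db4", 4)
      expect_lt(max(abs(dwt_reconstruct(d) - x)), 1e-8)
    }
    x <- stats::rnorm(64)
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(x, "db2", 3)) - x)), 1e-8)
    expect_lt(max(abs(dwt_reconstruct(dwt_decompose(x, "haar", 2)) - x)), 1e-8)
  })
  expect_error(dwt_decompose(rnorm(8), "db4", 4), "infeasible")
  expect_error(dwt_decompose(rnorm(64), "sym9", 2), "Unknown wavelet")
})

test_that("denoising is the identity without thresholding and preserves shape", {
  sig <- make_sine_signal(2400, noise_sd = 0.05, seed = 7)
  out <- dwt_denoise(sig, threshold_rule = "none")
  expect_equal(dim(out), dim(sig))
  expect_lt(max(abs(out$si_mm - sig$si_mm)), 1e-9)
  # constant signal passes through unchanged
  const <- resp_signal(tibble::tibble(time_s = (0:255) / 20,
                                      si_mm = 3, ap_mm = 1, lr_mm = 0.5),
                       sampling_rate_hz = 20)
  outc <- dwt_denoise(const)
  expect_lt(max(abs(outc$si_mm - 3)), 1e-9)
  expect_error(dwt_denoise(make_sine_signal(8), level = 4), "infeasible")
})

test_that("soft-universal thresholding strictly reduces error on a noisy sinusoid", {
  sig <- make_sine_signal(2400, freq_hz = 0.25, amp = 1, noise_sd = 0.05,
                          seed = 7)
  den <- dwt_denoise(sig)
  clean <- sig$clean_si_mm
  expect_lt(rmse(den$si_mm, clean), rmse(sig$si_mm, clean))
  # direct-formula RMSE for transparency of the check
  expect_equal(rmse(sig$si_mm, clean),
               sqrt(mean((sig$si_mm - clean)^2)))
})

test_that("cycle segmentation recovers trough-to-trough cycles", {
  # pure cosine, period 4 s, 120 s: 30 interior troughs -> 29 cycles
  t <- (0:2399) / 20
  x <- cos(2 * pi * t / 4)
  sig <- resp_signal(tibble::tibble(time_s = t, si_mm = x, ap_mm = 0.4 * x,
                                    lr_mm = 0.3 * x), 20,
                     nominal_period_s = 4)
  cyc <- segment_cycles(sig)
  expect_equal(nrow(cyc), 29)
  # troughs at t = 2, 6, ... within one sample
  expect_true(all(abs(cyc$start_time_s - (4 * (0:28) + 2)) <= 0.05 + 1e-9))
  expect_true(all(abs(cyc$erom_si_mm - 2) < 1e-6))

  # record shorter than one period: no cycles, not an error
  short <- resp_signal(tibble::tibble(time_s = (0:59) / 20,
                                      si_mm = cos(2 * pi * (0:59) / 80),
                                      ap_mm = 0, lr_mm = 0), 20,
                       nominal_period_s = 4)
  expect_equal(nrow(segment_cycles(short)), 0)
})

test_that("segmentation of a jittered record matches the exhaustive trough oracle", {
  rec <- generate_signal(6, generator_config(), seed = 11)
  sig <- dwt_denoise(rec$signal)
  hint <- attr(sig, "nominal_period_s")
  cyc <- segment_cycles(sig, period_hint_s = hint)
  sel <- oracle_troughs(sig$si_mm, min_sep = 0.5 * hint * 20,
                        min_prom = 0.1 * (max(sig$si_mm) - min(sig$si_mm)))
  expect_equal(nrow(cyc), length(sel) - 1)
  expect_equal(cyc$start_idx, sel[-length(sel)])
})

test_that("period estimation recovers the dominant breathing period", {
  sig <- make_sine_signal(2400, freq_hz = 0.25, noise_sd = 0.02, seed = 4)
  expect_lt(abs(estimate_period(sig) - 4), 0.2)
})

test_that("per-record min-max normalization maps to [0, 1] and inverts exactly", {
  t <- (0:255) / 20
  x <- 5 * sin(2 * pi * t / 4)   # spans [-5, 5]
  sig <- resp_signal(tibble::tibble(time_s = t, si_mm = x, ap_mm = 0.4 * x,
                                    lr_mm = 0.3 * x), 20)
  norm <- normalize_signal(sig, method = "minmax")
  expect_equal(range(norm$si_mm), c(0, 1))
  expect_equal(norm$si_mm[x == 0][1], 0.5)
  back <- denormalize_signal(norm)
  expect_lt(max(abs(back$si_mm - sig$si_mm)), 1e-9)

  rec <- generate_signal(7, generator_config(), seed = 5)
  norm2 <- normalize_signal(rec$signal, method = "minmax")
  back2 <- denormalize_signal(norm2)
  expect_lt(max(abs(as.matrix(back2[, -1]) - as.matrix(rec$signal[, -1]))),
            1e-9)

  # constant axis: mapped to 0.5 and flagged
  const <- resp_signal(tibble::tibble(time_s = t, si_mm = x, ap_mm = 2,
                                      lr_mm = x), 20)
  nc <- normalize_signal(const, method = "minmax")
  expect_true(all(nc$ap_mm == 0.5))
  expect_true(attr(nc, "norm_transform")$degenerate[2])

  # fixed method: one shared affine map, also exactly invertible
  nf <- normalize_signal(rec$signal, method = "fixed")
  expect_lt(max(abs(denormalize_signal(nf)$si_mm - rec$signal$si_mm)), 1e-12)
})

test_that("window counts follow N - W - max(horizon) + 1 and targets align", {
  rec <- generate_signal(5, generator_config(), seed = 9)
  spec <- window_spec()   # W = 120, horizons 1/3/6/10, stride 1
  w <- make_windows(dwt_denoise(rec$signal), rec$label, spec)
  expect_equal(n_windows(w), 2400 - 120 - 10 + 1)

  # short signals: exactly one window, then rejection
  short_label <- tibble::tibble(motion_class = 1L, excessive = FALSE)
  w1 <- make_windows(make_sine_signal(130, seed = 2), short_label, spec)
  expect_equal(n_windows(w1), 1)
  expect_error(make_windows(make_sine_signal(129, seed = 2), short_label,
                            spec),
               "window")

  # the horizon targets are the normalized clean trace at start + W - 1 + h
  norm <- normalize_signal(dwt_denoise(rec$signal), method = "fixed")
  cln <- signal_matrix(norm, clean = TRUE)
  i <- 57
  s <- w$meta$window_start[i]
  for (hi in seq_along(spec$horizons_samples)) {
    h <- spec$horizons_samples[hi]
    expect_equal(w$reg_targets[i, (hi - 1) * 3 + 1:3],
                 unname(cln[s + 119 + h, ]))
  }
  # reconstruction target is the clean window itself
  expect_equal(matrix(w$recon_targets[i, ], 120, 3),
               unname(cln[s:(s + 119), ]))
  # window stride and subsetting
  w2 <- make_windows(dwt_denoise(rec$signal), rec$label,
                     window_spec(stride = 240))
  expect_equal(n_windows(w2), length(seq(1, 2271, by = 240)))
})

test_that("windowed inputs stay in [0, 1] under the fixed normalization", {
  ds <- simulate_breathing(8, seed = 6)
  w <- prepare_windows(ds, window_spec(stride = 300))
  expect_true(all(w$inputs >= 0 & w$inputs <= 1))
  expect_true(all(w$meta$motion_class %in% 1:4))
})

test_that("patient-wise splits never let a patient straddle partitions", {
  ds <- simulate_breathing(40, seed = 8)
  w <- prepare_windows(ds, window_spec(stride = 600))
  sp <- split_patients(w, seed = 3)
  pat <- sub("_.*$", "", w$meta$signal_id)
  expect_length(intersect(pat[sp$train], pat[sp$test]), 0)
  expect_length(intersect(pat[sp$train], pat[sp$val]), 0)
  expect_length(intersect(pat[sp$val], pat[sp$test]), 0)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), seq_len(n_windows(w)))
})
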