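# Independent brute-force oracles used by the tests. These deliberately use
# plain loops and no package internals, so they stay independent of the
# implementation paths they check.

# dilated convolution by definition: out[p] = sum_i F[p - d*i] * k[i], zero
# outside the sequence (indices here 1-based, i from 0).
oracle_dilated_conv <- function(x, kernel, d) {
  n <- length(x)
  out <- numeric(n)
  for (p in seq_len(n)) {
    acc <- 0
    for (i in seq_along(kernel) - 1L) {
      j <- p - d * i
      if (j >= 1) acc <- acc + x[j] * kernel[i + 1L]
    }
    out[p] <- acc
  }
  out
}

# all-pairs (Mann-Whitney) AUC with tie halving
oracle_auc_pairs <- function(scores, positive) {
  pos <- which(positive)
  neg <- which(!positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) total <- total + 1
      else if (scores[i] == scores[j]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# term-by-term composite loss
oracle_composite_loss <- function(probs, ycls, reg_pred, yreg, recon, yrec,
                                  exc_prob, yexc, w) {
  n <- nrow(probs)
  ce <- 0
  for (i in seq_len(n)) ce <- ce - log(probs[i, ycls[i]])
  ce <- ce / n
  mse <- 0
  for (i in seq_len(n)) for (j in seq_len(ncol(reg_pred))) {
    mse <- mse + (reg_pred[i, j] - yreg[i, j])^2
  }
  mse <- mse / (n * ncol(reg_pred))
  mae_ <- 0
  for (i in seq_len(n)) for (j in seq_len(ncol(recon))) {
    mae_ <- mae_ + abs(recon[i, j] - yrec[i, j])
  }
  mae_ <- mae_ / (n * ncol(recon))
  bce <- 0
  for (i in seq_len(n)) {
    p <- min(max(exc_prob[i], 1e-9), 1 - 1e-9)
    bce <- bce - (yexc[i] * log(p) + (1 - yexc[i]) * log(1 - p))
  }
  bce <- bce / n
  w[1] * ce + w[2] * mse + w[3] * mae_ + w[4] * bce
}

# Exhaustive trough scan with the same separation/prominence rules as
# segment_cycles, written as plain loops.
oracle_troughs <- function(x, min_sep, min_prom) {
  n <- length(x)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] - x[i - 1] < 0 && x[i + 1] - x[i] > 0) cand <- c(cand, i)
  }
  if (length(cand) == 0) return(integer(0))
  bounds <- c(1L, cand, n)
  keep <- integer(0)
  for (k in seq_along(cand)) {
    left_max <- -Inf
    for (j in bounds[k]:cand[k]) left_max <- max(left_max, x[j])
    right_max <- -Inf
    for (j in cand[k]:bounds[k + 2L]) right_max <- max(right_max, x[j])
    if (min(left_max, right_max) - x[cand[k]] >= min_prom) {
      keep <- c(keep, cand[k])
    }
  }
  if (length(keep) == 0) return(integer(0))
  sel <- keep[1]
  for (i in keep[-1]) {
    if (i - sel[length(sel)] >= min_sep) {
      sel <- c(sel, i)
    } else if (x[i] < x[sel[length(sel)]]) {
      sel[length(sel)] <- i
    }
  }
  sel
}

# per-cycle EROM label re-derivation from the clean trace
oracle_label <- function(signal, period_hint_s) {
  fs <- attr(signal, "sampling_rate_hz")
  m <- cbind(signal$clean_si_mm, signal$clean_ap_mm, signal$clean_lr_mm)
  x <- m[, 1]
  sel <- oracle_troughs(x, min_sep = 0.5 * period_hint_s * fs,
                        min_prom = 0.1 * (max(x) - min(x)))
  if (length(sel) < 2) return(NULL)
  erom <- matrix(0, length(sel) - 1, 3)
  for (k in seq_len(length(sel) - 1)) {
    for (a in 1:3) {
      seg <- m[sel[k]:sel[k + 1], a]
      erom[k, a] <- max(seg) - min(seg)
    }
  }
  colMeans(erom)
}

# fixtures shared across test files: one small irregular record and a tiny
# network configuration
tiny_net_config <- function(...) {
  motion_net_config(window_len = 16, channels = 4, dilations = c(1, 2),
                    hidden_size = 5, latent_dim = 3, decoder_hidden = 4,
                    n_horizons = 2, dropout = 0, ...)
}

make_sine_signal <- function(n, freq_hz = 0.25, fs = 20, amp = 1,
                             noise_sd = 0, seed = 1, clean = TRUE) {
  t <- (seq_len(n) - 1) / fs
  base <- amp * sin(2 * pi * freq_hz * t)
  withr::with_seed(seed, {
    noisy <- base + stats::rnorm(n, 0, noise_sd)
  })
  df <- tibble::tibble(time_s = t, si_mm = noisy, ap_mm = 0.4 * noisy,
                       lr_mm = 0.3 * noisy)
  if (clean) {
    df$clean_si_mm <- base
    df$clean_ap_mm <- 0.4 * base
    df$clean_lr_mm <- 0.3 * base
  }
  resp_signal(df, sampling_rate_hz = fs, signal_id = "sine",
              nominal_period_s = 1 / freq_hz)
}
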