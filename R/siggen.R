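#' Motion-range class bins
#'
#' Left-closed amplitude bins (mm) used for motion-range classification:
#' class 1 = \[0, 4), class 2 = \[4, 6), class 3 = \[6, 8), class 4 = \[8, Inf).
#' Each class is reported with a representative amplitude near its midpoint,
#' and amplitudes at or above 9 mm are additionally flagged as excessive
#' motion (beyond common planning margins and gating tolerances).
#'
#' @keywords internal
motion_class_edges <- function() c(0, 4, 6, 8, Inf)

motion_class_representatives <- function() c(3.99, 5.99, 7.99, 10.00)

#' Assign the motion-range class of an amplitude
#'
#' Maps a peak-to-trough motion amplitude (EROM, mm) to one of four
#' clinically motivated amplitude bins, its representative reporting value,
#' and the excessive-motion flag (amplitude >= 9 mm). Bins are left-closed:
#' an amplitude of exactly 4 mm falls in class 2.
#'
#' @param amplitude_mm Numeric vector of non-negative, finite amplitudes (mm).
#' @return A tibble with one row per amplitude and columns
#'   `amplitude_mm`, `motion_class` (integer 1-4),
#'   `representative_value_mm` (3.99, 5.99, 7.99 or 10.00) and
#'   `excessive` (logical).
#' @export
#' @examples
#' assign_motion_class(c(3.99, 4, 8.5, 9.5))
assign_motion_class <- function(amplitude_mm) {
  if (!is.numeric(amplitude_mm) || length(amplitude_mm) == 0) {
    rlang::abort("`amplitude_mm` must be a non-empty numeric vector.")
  }
  if (any(!is.finite(amplitude_mm)) || any(amplitude_mm < 0)) {
    rlang::abort("`amplitude_mm` must be finite and non-negative.")
  }
  cls <- findInterval(amplitude_mm, motion_class_edges(),
                      left.open = FALSE, rightmost.closed = FALSE)
  cls <- pmin(cls, 4L)
  tibble::tibble(
    amplitude_mm = amplitude_mm,
    motion_class = as.integer(cls),
    representative_value_mm = motion_class_representatives()[cls],
    excessive = amplitude_mm >= 9.0
  )
}

#' Generator configuration for synthetic respiratory signals
#'
#' Describes the quasi-periodic breathing model used by [generate_signal()]
#' and [simulate_breathing()]. The waveform follows the standard respiratory
#' motion model `z(t) = b * env(t) * (1/2 - cos^(2n)(theta(t)))`, a
#' cos-power trace with a sharp end-exhale trough and a flattened inhale
#' plateau; phase `theta` advances piecewise-linearly through per-cycle
#' periods so that period jitter joins cycles smoothly at the (zero-slope)
#' troughs. Irregularity enters through slow sinusoidal amplitude
#' modulation, per-cycle period jitter, sinusoidal baseline drift,
#' occasional cough-like transient bumps, and additive white measurement
#' noise.
#'
#' @param sampling_rate_hz Sampling rate (default 20 Hz so that 50 ms equals
#'   exactly one sample).
#' @param duration_s Record length in seconds (default 120, one bed
#'   position).
#' @param period_mean_s,period_sd_s Between-record breathing period
#'   distribution (s).
#' @param waveform_exponent Half-exponent n of the cos^(2n) waveform
#'   (default 2, i.e. cos^4).
#' @param axis_ratios AP and LR amplitudes as fractions of SI
#'   (default c(ap = 0.4, lr = 0.3)).
#' @param am_depth Amplitude-modulation depth (fractional, default 0.1).
#' @param am_period_s Amplitude-modulation period (default 25 s, a slow
#'   waxing-waning envelope over several breaths).
#' @param jitter_cv Per-cycle period jitter coefficient of variation
#'   (default 0.05).
#' @param drift_amplitude_mm,drift_period_s Sinusoidal baseline drift
#'   (defaults 0.3 mm, 60 s).
#' @param artifact_rate Expected number of transient (cough-like) artifacts
#'   per 120 s (default 0.2).
#' @param artifact_amplitude_mm,artifact_width_s Gaussian-bump artifact
#'   shape (defaults 2 mm, 0.3 s).
#' @param noise_sd_mm Additive white Gaussian noise s.d. (default 0.05 mm).
#' @param segments_per_patient Number of 120-s segments attributed to one
#'   synthetic patient by [simulate_breathing()] (default 4).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(sampling_rate_hz = 20,
                             duration_s = 120,
                             period_mean_s = 4.0,
                             period_sd_s = 0.5,
                             waveform_exponent = 2,
                             axis_ratios = c(ap = 0.4, lr = 0.3),
                             am_depth = 0.1,
                             am_period_s = 25,
                             jitter_cv = 0.05,
                             drift_amplitude_mm = 0.3,
                             drift_period_s = 60,
                             artifact_rate = 0.2,
                             artifact_amplitude_mm = 2,
                             artifact_width_s = 0.3,
                             noise_sd_mm = 0.05,
                             segments_per_patient = 4) {
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    period_mean_s = period_mean_s, period_sd_s = period_sd_s,
    waveform_exponent = waveform_exponent, axis_ratios = axis_ratios,
    am_depth = am_depth, am_period_s = am_period_s, jitter_cv = jitter_cv,
    drift_amplitude_mm = drift_amplitude_mm, drift_period_s = drift_period_s,
    artifact_rate = artifact_rate,
    artifact_amplitude_mm = artifact_amplitude_mm,
    artifact_width_s = artifact_width_s,
    noise_sd_mm = noise_sd_mm,
    segments_per_patient = segments_per_patient
  )
  nonneg <- c("period_sd_s", "am_depth", "jitter_cv", "drift_amplitude_mm",
              "artifact_rate", "artifact_amplitude_mm", "noise_sd_mm")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) {
      rlang::abort(paste0("`", f, "` must be non-negative."))
    }
  }
  for (f in c("sampling_rate_hz", "duration_s", "period_mean_s",
              "am_period_s", "drift_period_s", "artifact_width_s")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      rlang::abort(paste0("`", f, "` must be positive."))
    }
  }
  # latency bins must map to whole samples: 50 ms must be an integer count
  if (abs(sampling_rate_hz * 0.05 - round(sampling_rate_hz * 0.05)) > 1e-9 ||
      sampling_rate_hz * 0.05 < 1) {
    rlang::abort("`sampling_rate_hz` * 0.05 s must be a whole number of samples >= 1.")
  }
  structure(cfg, class = "generator_config")
}

#' Generate one synthetic respiratory record with its motion label
#'
#' Simulates a quasi-periodic multi-axis breathing trace whose SI-axis mean
#' per-cycle peak-to-trough amplitude (EROM) is close to
#' `target_amplitude_mm`; AP and LR are scaled copies per
#' `config$axis_ratios`. The motion label is *derived from the generated
#' clean trace* (not from the target): [segment_cycles()] delimits breathing
#' cycles on the clean SI axis and the label's per-axis EROM is the mean
#' per-cycle max - min. The dominant amplitude (max over axes) is binned by
#' [assign_motion_class()].
#'
#' @param target_amplitude_mm Positive target SI peak-to-trough amplitude (mm).
#' @param config A [generator_config()].
#' @param seed Integer seed; identical `(target, config, seed)` reproduce
#'   the record bit for bit.
#' @return A list with elements `signal` (a [resp_signal()] with clean
#'   columns populated) and `label` (a one-row tibble with
#'   `erom_si_mm`, `erom_ap_mm`, `erom_lr_mm`, `dominant_amplitude_mm`,
#'   `motion_class`, `representative_value_mm`, `excessive`).
#' @export
#' @examples
#' rec <- generate_signal(5, generator_config(), seed = 7)
#' rec$label
generate_signal <- function(target_amplitude_mm, config = generator_config(),
                            seed = 1L, signal_id = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.numeric(target_amplitude_mm) || length(target_amplitude_mm) != 1 ||
      !is.finite(target_amplitude_mm) || target_amplitude_mm <= 0) {
    rlang::abort("`target_amplitude_mm` must be a single positive number.")
  }
  if (config$duration_s < config$period_mean_s) {
    rlang::abort("`duration_s` must cover at least one breathing period.")
  }
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  b <- target_amplitude_mm

  withr::with_seed(as.integer(seed), {
    # record-level breathing period, clamped to a physiological range
    tau0 <- stats::rnorm(1, config$period_mean_s, config$period_sd_s)
    tau0 <- min(max(tau0, max(1.5, config$period_mean_s - 2 * config$period_sd_s)),
                config$period_mean_s + 2 * config$period_sd_s)
    # initial phase quantized to the sample grid so that, in the fully
    # regular case, troughs and peaks fall exactly on samples
    spc <- round(tau0 * fs)                       # samples per cycle
    phase0 <- pi * sample.int(spc, 1) / spc

    # per-cycle periods with jitter; phase advances by pi per cycle and is
    # continuous (the cos^(2n) trough has zero slope, so joins are smooth)
    n_cycles <- ceiling(config$duration_s / tau0) + 3L
    tau_k <- tau0 * (1 + config$jitter_cv * stats::rnorm(n_cycles))
    tau_k <- pmax(tau_k, 0.5 * tau0)
    cycle_start <- c(0, cumsum(tau_k)) - phase0 / pi * tau_k[1]
    theta <- numeric(n)
    k <- 1L
    for (i in seq_len(n)) {
      while (k < n_cycles && t[i] >= cycle_start[k + 1L]) k <- k + 1L
      theta[i] <- pi * ((k - 1L) + (t[i] - cycle_start[k]) / tau_k[k])
    }

    env <- 1 + config$am_depth *
      sin(2 * pi * t / config$am_period_s + stats::runif(1, 0, 2 * pi))
    base <- b * env * (0.5 - cos(theta)^(2 * config$waveform_exponent))

    drift <- if (config$drift_amplitude_mm > 0) {
      config$drift_amplitude_mm *
        sin(2 * pi * t / config$drift_period_s + stats::runif(1, 0, 2 * pi))
    } else {
      numeric(n)
    }

    bumps <- numeric(n)
    n_art <- stats::rpois(1, config$artifact_rate * config$duration_s / 120)
    if (n_art > 0) {
      for (j in seq_len(n_art)) {
        centre <- stats::runif(1, 0, config$duration_s)
        amp <- config$artifact_amplitude_mm * stats::runif(1, 0.5, 1.5) *
          sample(c(-1, 1), 1)
        bumps <- bumps + amp * exp(-(t - centre)^2 / (2 * config$artifact_width_s^2))
      }
    }

    clean_si <- base + drift + bumps
    clean <- cbind(si = clean_si,
                   ap = config$axis_ratios[["ap"]] * clean_si,
                   lr = config$axis_ratios[["lr"]] * clean_si)
    noise <- matrix(stats::rnorm(3 * n, 0, config$noise_sd_mm), ncol = 3)
    samples <- clean + noise
  })

  if (is.null(signal_id)) signal_id <- paste0("sig_seed", seed)
  sig <- resp_signal(
    tibble::tibble(
      time_s = t,
      si_mm = samples[, 1], ap_mm = samples[, 2], lr_mm = samples[, 3],
      clean_si_mm = clean[, 1], clean_ap_mm = clean[, 2],
      clean_lr_mm = clean[, 3]
    ),
    sampling_rate_hz = fs, signal_id = signal_id, nominal_period_s = tau0
  )
  list(signal = sig, label = label_from_clean(sig))
}

#' Derive the motion label of a record from its clean trace
#'
#' Segments breathing cycles on the clean SI axis ([segment_cycles()]) and
#' computes the mean per-cycle EROM (max - min) per axis; the dominant
#' amplitude (max over axes) determines the class via
#' [assign_motion_class()].
#'
#' @param signal A [resp_signal()] with clean columns.
#' @return A one-row label tibble.
#' @export
label_from_clean <- function(signal) {
  cycles <- segment_cycles(signal, use_clean = TRUE)
  if (nrow(cycles) == 0) {
    rlang::abort("Cannot label a record with fewer than one complete breathing cycle.")
  }
  erom <- c(mean(cycles$erom_si_mm), mean(cycles$erom_ap_mm),
            mean(cycles$erom_lr_mm))
  dom <- max(erom)
  cls <- assign_motion_class(dom)
  tibble::tibble(
    erom_si_mm = erom[1], erom_ap_mm = erom[2], erom_lr_mm = erom[3],
    dominant_amplitude_mm = dom,
    motion_class = cls$motion_class,
    representative_value_mm = cls$representative_value_mm,
    excessive = cls$excessive
  )
}

# amplitude sampling ranges per class: uniform within the bin, with a small
# interior margin so that the realized (trace-derived) EROM stays inside the
# intended bin despite amplitude modulation, drift and artifacts
class_amplitude_ranges <- function() {
  matrix(c(0.5, 3.75,
           4.10, 5.90,
           6.10, 7.75,
           8.10, 15.0), ncol = 2, byrow = TRUE)
}

#' Simulate a labelled dataset of respiratory records
#'
#' Generates `n_signals` 120-s records organised into synthetic patients
#' (`segments_per_patient` records each). Every patient is assigned a
#' motion-range class by the mixture weights and a base amplitude drawn
#' uniformly within that class's bin (class 4 on \[8, 15\] mm, reflecting
#' free-breathing lung-tumor motion of 10-15 mm); all segments of a patient
#' share the base amplitude, so patient-wise splits are meaningful.
#' Per-record seeds are derived from the master seed by a fixed counter
#' scheme (`(seed * 1000003 + i) mod (2^31 - 1)`), making the dataset fully
#' reproducible.
#'
#' @param n_signals Number of records (positive integer).
#' @param class_mixture Four non-negative weights, normalized to sum to 1.
#' @param config A [generator_config()].
#' @param seed Master integer seed.
#' @return A tibble (one row per record) with columns `signal_id`,
#'   `patient_id`, `target_amplitude_mm`, `seed`, the label columns of
#'   [label_from_clean()], and a `signal` list-column of [resp_signal()]
#'   objects.
#' @export
#' @examples
#' ds <- simulate_breathing(8, seed = 1)
#' dplyr::count(ds, motion_class)
simulate_breathing <- function(n_signals,
                               class_mixture = c(0.25, 0.25, 0.25, 0.25),
                               config = generator_config(),
                               seed = 1L) {
  if (!is.numeric(n_signals) || length(n_signals) != 1 || n_signals <= 0 ||
      n_signals != round(n_signals)) {
    rlang::abort("`n_signals` must be a positive integer.")
  }
  if (length(class_mixture) != 4 || any(class_mixture < 0) ||
      sum(class_mixture) <= 0) {
    rlang::abort("`class_mixture` must be 4 non-negative weights, not all zero.")
  }
  mix <- class_mixture / sum(class_mixture)
  spp <- config$segments_per_patient
  n_patients <- ceiling(n_signals / spp)

  ranges <- class_amplitude_ranges()
  withr::with_seed(as.integer(seed), {
    pat_class <- sample.int(4L, n_patients, replace = TRUE, prob = mix)
    pat_amp <- ranges[pat_class, 1] +
      stats::runif(n_patients) * (ranges[pat_class, 2] - ranges[pat_class, 1])
  })

  idx <- seq_len(n_signals)
  patient <- ((idx - 1) %/% spp) + 1L
  rec_seed <- as.integer((as.numeric(seed) * 1000003 + idx) %% 2147483647)

  records <- purrr::map(idx, function(i) {
    sid <- sprintf("p%03d_s%02d", patient[i], ((i - 1) %% spp) + 1L)
    rec <- generate_signal(pat_amp[patient[i]], config, seed = rec_seed[i],
                           signal_id = sid)
    dplyr::bind_cols(
      tibble::tibble(signal_id = sid,
                     patient_id = sprintf("p%03d", patient[i]),
                     target_amplitude_mm = pat_amp[patient[i]],
                     seed = rec_seed[i]),
      rec$label,
      tibble::tibble(signal = list(rec$signal))
    )
  })
  dplyr::bind_rows(records)
}

#' Manifest of a simulated dataset (labels without the signals)
#'
#' @param dataset Output of [simulate_breathing()].
#' @return The dataset tibble without the `signal` list-column.
#' @export
dataset_manifest <- function(dataset) {
  dplyr::select(dataset, -dplyr::any_of("signal"))
}
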