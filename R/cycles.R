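#' Estimate the dominant breathing period of a signal
#'
#' Autocorrelation-based estimate on the SI axis: the lag (between 1 s and
#' 12 s) that maximizes the autocorrelation is taken as the period.
#'
#' @param signal A [resp_signal()].
#' @return Period estimate in seconds.
#' @export
estimate_period <- function(signal) {
  fs <- attr(signal, "sampling_rate_hz")
  x <- signal$si_mm - mean(signal$si_mm)
  max_lag <- min(nrow(signal) - 1L, as.integer(12 * fs))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[, 1, 1]
  lo <- as.integer(fs) + 1L   # skip lags below 1 s
  if (lo >= length(ac)) return(nrow(signal) / fs)
  lag <- which.max(ac[(lo + 1L):length(ac)]) + lo - 1L
  lag / fs
}

find_local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  which(d[-length(d)] < 0 & d[-1] > 0) + 1L
}

#' Segment a respiratory signal into breathing cycles
#'
#' Breathing cycles are delimited by successive end-exhale troughs on the
#' SI axis (the gating convention anchors at expiration). Troughs are local
#' minima that (i) have prominence of at least `prominence_frac` times the
#' record's SI amplitude range, where the prominence of a candidate is the
#' smaller of the highest excursions between it and its neighbouring
#' candidates, and (ii) are separated by at least `min_separation_frac`
#' times the nominal period; when two qualifying troughs are closer than
#' that, the deeper one is kept.
#'
#' @param signal A [resp_signal()].
#' @param use_clean Segment on the clean trace when available (recommended
#'   for labelling); per-cycle EROM is then also computed on the clean
#'   trace.
#' @param period_hint_s Nominal breathing period (s); defaults to the
#'   signal's `nominal_period_s` attribute or, failing that, to
#'   [estimate_period()].
#' @param min_separation_frac Minimum trough separation as a fraction of
#'   the nominal period (default 0.5).
#' @param prominence_frac Minimum prominence as a fraction of the record's
#'   amplitude range (default 0.1).
#' @return A tibble with one row per complete trough-to-trough cycle:
#'   `cycle`, `start_idx`, `end_idx`, `start_time_s`, `end_time_s`,
#'   `period_s` and per-axis `erom_*_mm` (max - min within the cycle).
#'   Records with fewer than two qualifying troughs yield zero rows.
#' @export
segment_cycles <- function(signal, use_clean = FALSE, period_hint_s = NULL,
                           min_separation_frac = 0.5, prominence_frac = 0.1) {
  stopifnot(inherits(signal, "resp_signal"))
  fs <- attr(signal, "sampling_rate_hz")
  m <- signal_matrix(signal, clean = use_clean && has_clean(signal))
  x <- m[, "si"]
  if (is.null(period_hint_s)) {
    period_hint_s <- attr(signal, "nominal_period_s")
    if (is.null(period_hint_s)) period_hint_s <- estimate_period(signal)
  }

  troughs <- select_troughs(x, min_sep = min_separation_frac * period_hint_s * fs,
                            min_prom = prominence_frac * (max(x) - min(x)))
  empty <- tibble::tibble(
    cycle = integer(0), start_idx = integer(0), end_idx = integer(0),
    start_time_s = numeric(0), end_time_s = numeric(0), period_s = numeric(0),
    erom_si_mm = numeric(0), erom_ap_mm = numeric(0), erom_lr_mm = numeric(0)
  )
  if (length(troughs) < 2) return(empty)

  starts <- troughs[-length(troughs)]
  ends <- troughs[-1]
  erom <- vapply(seq_along(starts), function(i) {
    seg <- m[starts[i]:ends[i], , drop = FALSE]
    apply(seg, 2, function(v) max(v) - min(v))
  }, numeric(3))
  tibble::tibble(
    cycle = seq_along(starts),
    start_idx = starts, end_idx = ends,
    start_time_s = signal$time_s[starts], end_time_s = signal$time_s[ends],
    period_s = (ends - starts) / fs,
    erom_si_mm = erom[1, ], erom_ap_mm = erom[2, ], erom_lr_mm = erom[3, ]
  )
}

# Trough selection used by segment_cycles: prominence filter on strict local
# minima, then greedy minimum-separation enforcement keeping the deeper
# trough of any too-close pair.
select_troughs <- function(x, min_sep, min_prom) {
  cand <- find_local_minima(x)
  if (length(cand) == 0) return(integer(0))
  n <- length(x)
  bounds <- c(1L, cand, n)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    left_max <- max(x[bounds[i]:cand[i]])
    right_max <- max(x[cand[i]:bounds[i + 2L]])
    keep[i] <- (min(left_max, right_max) - x[cand[i]]) >= min_prom
  }
  cand <- cand[keep]
  if (length(cand) == 0) return(integer(0))
  sel <- cand[1]
  for (i in cand[-1]) {
    if (i - sel[length(sel)] >= min_sep) {
      sel <- c(sel, i)
    } else if (x[i] < x[sel[length(sel)]]) {
      sel[length(sel)] <- i
    }
  }
  sel
}

#' Normalize a respiratory signal to the unit interval
#'
#' Two methods are available. `"fixed"` (the pipeline default) applies one
#' affine map shared by all records and axes, taking `fixed_range_mm`
#' (default -10..10 mm, spanning free-breathing lung-tumor motion) to
#' \[0, 1\]; it preserves absolute amplitude information, which the
#' motion-range classifier needs. `"minmax"` maps each axis's combined
#' (observed + clean) range to \[0, 1\] per record; a constant axis is
#' mapped to 0.5 and flagged degenerate. Both transforms are stored on the
#' result and are exactly invertible via [denormalize_signal()].
#'
#' @param signal A [resp_signal()].
#' @param method `"fixed"` or `"minmax"`.
#' @param fixed_range_mm Length-2 range mapped to \[0, 1\] by the fixed
#'   method.
#' @return The normalized signal with a `norm_transform` attribute (tibble:
#'   `axis`, `offset_mm`, `scale_mm`, `degenerate`); values map as
#'   `(x - offset_mm) / scale_mm`.
#' @export
normalize_signal <- function(signal, method = c("fixed", "minmax"),
                             fixed_range_mm = c(-10, 10)) {
  method <- match.arg(method)
  stopifnot(inherits(signal, "resp_signal"))
  out <- signal
  axes <- axis_cols()
  tr <- tibble::tibble(axis = c("si", "ap", "lr"), offset_mm = NA_real_,
                       scale_mm = NA_real_, degenerate = FALSE)
  for (a in seq_along(axes)) {
    cols <- axes[a]
    if (has_clean(signal)) cols <- c(cols, clean_cols()[a])
    if (method == "fixed") {
      off <- fixed_range_mm[1]
      sc <- diff(fixed_range_mm)
    } else {
      rng <- range(unlist(signal[cols]))
      off <- rng[1]
      sc <- diff(rng)
      if (sc <= 0) {
        tr$degenerate[a] <- TRUE
        off <- rng[1] - 0.5
        sc <- 1
      }
    }
    tr$offset_mm[a] <- off
    tr$scale_mm[a] <- sc
    for (col in cols) out[[col]] <- (signal[[col]] - off) / sc
  }
  attr(out, "norm_transform") <- tr
  attr(out, "normalized") <- TRUE
  out
}

#' Invert [normalize_signal()]
#'
#' @param signal A normalized [resp_signal()] carrying a `norm_transform`
#'   attribute.
#' @return The signal in millimetres; round trips are exact to numerical
#'   precision.
#' @export
denormalize_signal <- function(signal) {
  tr <- attr(signal, "norm_transform")
  if (is.null(tr)) rlang::abort("Signal carries no `norm_transform` attribute.")
  out <- signal
  axes <- axis_cols()
  for (a in seq_along(axes)) {
    cols <- axes[a]
    if (has_clean(signal)) cols <- c(cols, clean_cols()[a])
    for (col in cols) out[[col]] <- signal[[col]] * tr$scale_mm[a] + tr$offset_mm[a]
  }
  attr(out, "norm_transform") <- NULL
  attr(out, "normalized") <- NULL
  out
}
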