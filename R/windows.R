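#' Windowing specification
#'
#' @param window_len_samples Input window length (default 120 samples = 6 s
#'   at 20 Hz, about 1.5 breathing cycles).
#' @param horizons_samples Strictly increasing prediction horizons in
#'   samples (default `c(1, 3, 6, 10)`, i.e. 50/150/300/500 ms at 20 Hz).
#' @param horizon_labels_ms Latency-bin labels paired with the horizons.
#' @param stride Window stride in samples (default 1).
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(window_len_samples = 120,
                        horizons_samples = c(1, 3, 6, 10),
                        horizon_labels_ms = c("40-50", "100-150",
                                              "200-300", "400-500"),
                        stride = 1) {
  if (any(diff(horizons_samples) <= 0) || any(horizons_samples < 1)) {
    rlang::abort("`horizons_samples` must be strictly increasing positive integers.")
  }
  if (length(horizon_labels_ms) != length(horizons_samples)) {
    rlang::abort("One latency label per horizon is required.")
  }
  if (window_len_samples < 1 || stride < 1) {
    rlang::abort("`window_len_samples` and `stride` must be positive.")
  }
  structure(list(window_len_samples = as.integer(window_len_samples),
                 horizons_samples = as.integer(horizons_samples),
                 horizon_labels_ms = horizon_labels_ms,
                 stride = as.integer(stride)),
            class = "window_spec")
}

#' Convert a labelled signal into windowed supervised examples
#'
#' Slides a window of `spec$window_len_samples` over the (normalized)
#' observed trace. Each window carries the record's motion class and
#' excessive flag, the clean-trace future position at every horizon for
#' every axis (the prediction targets), and the clean window itself (the
#' reconstruction target). At stride 1 the number of windows is
#' `N - window_len - max(horizon) + 1`.
#'
#' @param signal A [resp_signal()] (typically denoised) with clean columns;
#'   if clean columns are absent the observed trace doubles as the target.
#' @param label A one-row label tibble (see [label_from_clean()]) or `NULL`
#'   to derive it from the clean trace.
#' @param spec A [window_spec()].
#' @param normalization Normalization method passed to
#'   [normalize_signal()]; the default `"fixed"` global map preserves
#'   amplitude information across records.
#' @param fixed_range_mm Range for the fixed normalization.
#' @return A `windowed_dataset`: a list with
#'   \describe{
#'     \item{inputs}{array `[n_windows, window_len, 3]` of normalized
#'       observed samples,}
#'     \item{reg_targets}{matrix `[n_windows, 3 * n_horizons]` of normalized
#'       clean future positions, horizon-major (SI, AP, LR within each
#'       horizon),}
#'     \item{recon_targets}{matrix `[n_windows, window_len * 3]` of the
#'       normalized clean window (time-major per axis),}
#'     \item{meta}{tibble with `signal_id`, `window_start`, `motion_class`,
#'       `excessive`,}
#'     \item{spec, transforms}{the window spec and per-record normalization
#'       transforms.}
#'   }
#' @export
make_windows <- function(signal, label = NULL, spec = window_spec(),
                         normalization = c("fixed", "minmax"),
                         fixed_range_mm = c(-10, 10)) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(signal, "resp_signal"), inherits(spec, "window_spec"))
  n <- nrow(signal)
  w <- spec$window_len_samples
  hmax <- max(spec$horizons_samples)
  if (n < w + hmax) {
    rlang::abort(sprintf(
      "Signal too short for windowing: length %d < window (%d) + max horizon (%d).",
      n, w, hmax))
  }
  if (is.null(label)) {
    label <- if (has_clean(signal)) label_from_clean(signal) else
      rlang::abort("`label` is required when the signal has no clean trace.")
  }

  norm <- normalize_signal(signal, method = normalization,
                           fixed_range_mm = fixed_range_mm)
  obs <- signal_matrix(norm, clean = FALSE)
  cln <- if (has_clean(norm)) signal_matrix(norm, clean = TRUE) else obs

  starts <- seq(1L, n - w - hmax + 1L, by = spec$stride)
  nw <- length(starts)
  nh <- length(spec$horizons_samples)

  inputs <- array(0, dim = c(nw, w, 3))
  reg <- matrix(0, nw, 3 * nh)
  recon <- matrix(0, nw, w * 3)
  for (i in seq_len(nw)) {
    s <- starts[i]
    win <- obs[s:(s + w - 1L), , drop = FALSE]
    inputs[i, , ] <- win
    cwin <- cln[s:(s + w - 1L), , drop = FALSE]
    recon[i, ] <- as.vector(cwin)          # column-major: si block, ap, lr
    last <- s + w - 1L
    for (hi in seq_len(nh)) {
      reg[i, (hi - 1L) * 3L + 1:3] <- cln[last + spec$horizons_samples[hi], ]
    }
  }

  structure(list(
    inputs = inputs, reg_targets = reg, recon_targets = recon,
    meta = tibble::tibble(
      signal_id = attr(signal, "signal_id"),
      window_start = starts,
      motion_class = label$motion_class,
      excessive = label$excessive
    ),
    spec = spec,
    transforms = tibble::tibble(
      signal_id = attr(signal, "signal_id"),
      transform = list(attr(norm, "norm_transform"))
    )
  ), class = "windowed_dataset")
}

#' Number of windows in a windowed dataset
#' @param x A `windowed_dataset`.
#' @export
n_windows <- function(x) nrow(x$meta)

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset: %d windows of %d samples x 3 axes, horizons [%s], %d record(s)>\n",
    n_windows(x), x$spec$window_len_samples,
    paste(x$spec$horizons_samples, collapse = ", "),
    length(unique(x$meta$signal_id))))
  invisible(x)
}

#' Combine windowed datasets from several records
#'
#' @param datasets A list of `windowed_dataset` objects sharing one
#'   [window_spec()].
#' @return A single `windowed_dataset`.
#' @export
bind_windows <- function(datasets) {
  stopifnot(length(datasets) > 0)
  spec <- datasets[[1]]$spec
  same <- vapply(datasets, function(d) identical(d$spec, spec), logical(1))
  if (!all(same)) rlang::abort("All datasets must share the same window spec.")
  inputs <- do.call(abind_first, lapply(datasets, `[[`, "inputs"))
  structure(list(
    inputs = inputs,
    reg_targets = do.call(rbind, lapply(datasets, `[[`, "reg_targets")),
    recon_targets = do.call(rbind, lapply(datasets, `[[`, "recon_targets")),
    meta = dplyr::bind_rows(lapply(datasets, `[[`, "meta")),
    spec = spec,
    transforms = dplyr::bind_rows(lapply(datasets, `[[`, "transforms"))
  ), class = "windowed_dataset")
}

# bind 3-d arrays along the first dimension
abind_first <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], integer(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (a in arrays) {
    k <- dim(a)[1]
    out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

#' Subset a windowed dataset by window index
#'
#' @param x A `windowed_dataset`.
#' @param idx Integer or logical index over windows.
#' @return A `windowed_dataset` with the selected windows.
#' @export
subset_windows <- function(x, idx) {
  structure(list(
    inputs = x$inputs[idx, , , drop = FALSE],
    reg_targets = x$reg_targets[idx, , drop = FALSE],
    recon_targets = x$recon_targets[idx, , drop = FALSE],
    meta = x$meta[idx, ],
    spec = x$spec,
    transforms = x$transforms
  ), class = "windowed_dataset")
}

#' Build windows for a whole simulated dataset
#'
#' Denoises every record, windows it, and binds the result; the
#' one-stop preprocessing step from [simulate_breathing()] output to
#' training examples.
#'
#' @param dataset Tibble from [simulate_breathing()].
#' @param spec A [window_spec()].
#' @param denoise Apply [dwt_denoise()] first (default TRUE).
#' @param ... Passed to [make_windows()].
#' @return A `windowed_dataset` covering all records.
#' @export
prepare_windows <- function(dataset, spec = window_spec(), denoise = TRUE, ...) {
  parts <- purrr::map(seq_len(nrow(dataset)), function(i) {
    sig <- dataset$signal[[i]]
    if (denoise) sig <- dwt_denoise(sig)
    make_windows(sig, label = dataset[i, ], spec = spec, ...)
  })
  bind_windows(parts)
}

#' Patient-wise train/validation/test split
#'
#' Splits window indices by patient (the prefix of `signal_id` up to the
#' first underscore) so that no patient straddles splits, avoiding subject
#' leakage.
#'
#' @param windows A `windowed_dataset`.
#' @param test_frac Fraction of patients held out for testing (default 0.2).
#' @param val_frac Fraction of *training* patients reserved for
#'   early-stopping validation (default 0.1).
#' @param seed Integer seed for the patient shuffle.
#' @return A list of integer index vectors `train`, `val`, `test` and the
#'   patient assignment tibble.
#' @export
split_patients <- function(windows, test_frac = 0.2, val_frac = 0.1, seed = 1L) {
  patient <- sub("_.*$", "", windows$meta$signal_id)
  patients <- sort(unique(patient))
  np <- length(patients)
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(patients)
  })
  n_test <- max(1L, round(test_frac * np))
  test_p <- shuffled[seq_len(n_test)]
  rest <- shuffled[-seq_len(n_test)]
  n_val <- max(1L, round(val_frac * length(rest)))
  val_p <- rest[seq_len(n_val)]
  train_p <- rest[-seq_len(n_val)]
  assignment <- tibble::tibble(
    patient_id = c(train_p, val_p, test_p),
    split = rep(c("train", "val", "test"),
                c(length(train_p), length(val_p), length(test_p)))
  )
  list(
    train = which(patient %in% train_p),
    val = which(patient %in% val_p),
    test = which(patient %in% test_p),
    assignment = assignment
  )
}
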