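#' Construct a respiratory signal
#'
#' A `resp_signal` is a tibble holding a multi-axis respiratory displacement
#' trace, one row per time sample, with the three anatomical axes
#' superior-inferior (SI), anterior-posterior (AP) and left-right (LR) in
#' millimetres. Optional `clean_*` columns carry the noise-free component of
#' the trace when it is known (e.g. for simulated signals), which downstream
#' stages use as prediction and reconstruction targets.
#'
#' @param data A data frame with columns `time_s`, `si_mm`, `ap_mm`, `lr_mm`
#'   and optionally `clean_si_mm`, `clean_ap_mm`, `clean_lr_mm`. Additional
#'   columns are preserved.
#' @param sampling_rate_hz Sampling rate in Hz (positive).
#' @param signal_id Character identifier of the record.
#' @param nominal_period_s Optional nominal breathing period in seconds,
#'   carried as metadata when known (used as a hint by [segment_cycles()]).
#'
#' @return A tibble of class `resp_signal` with attributes
#'   `sampling_rate_hz`, `signal_id`, `duration_s` and (optionally)
#'   `nominal_period_s`.
#' @export
#' @examples
#' t <- seq(0, 10 - 0.05, by = 0.05)
#' sig <- resp_signal(
#'   tibble::tibble(time_s = t, si_mm = sin(t), ap_mm = 0.4 * sin(t),
#'                  lr_mm = 0.3 * sin(t)),
#'   sampling_rate_hz = 20, signal_id = "demo"
#' )
resp_signal <- function(data, sampling_rate_hz, signal_id = "signal",
                        nominal_period_s = NULL) {
  data <- tibble::as_tibble(data)
  required <- c("time_s", "si_mm", "ap_mm", "lr_mm")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("resp_signal is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    rlang::abort("`sampling_rate_hz` must be a single positive number.")
  }
  num_cols <- intersect(c(required, paste0("clean_", required[-1])), names(data))
  for (col in num_cols) {
    if (!all(is.finite(data[[col]]))) {
      rlang::abort(paste0("Column `", col, "` contains non-finite values."))
    }
  }
  structure(
    data,
    class = c("resp_signal", class(tibble::tibble())),
    sampling_rate_hz = sampling_rate_hz,
    signal_id = as.character(signal_id),
    duration_s = nrow(data) / sampling_rate_hz,
    nominal_period_s = nominal_period_s
  )
}

#' @export
print.resp_signal <- function(x, ...) {
  cat(sprintf("<resp_signal '%s': %d samples @ %g Hz (%.1f s)%s>\n",
              attr(x, "signal_id"), nrow(x), attr(x, "sampling_rate_hz"),
              attr(x, "duration_s"),
              if (has_clean(x)) ", with clean trace" else ""))
  NextMethod()
}

axis_cols <- function() c("si_mm", "ap_mm", "lr_mm")
clean_cols <- function() paste0("clean_", axis_cols())

has_clean <- function(signal) all(clean_cols() %in% names(signal))

#' Extract the displacement matrix of a signal
#'
#' @param signal A [resp_signal()].
#' @param clean Return the clean (noise-free) component instead of the
#'   observed trace. Errors if the signal carries no clean columns.
#' @return A numeric matrix `[n_timepoints x 3]` with columns SI, AP, LR.
#' @export
signal_matrix <- function(signal, clean = FALSE) {
  cols <- if (clean) clean_cols() else axis_cols()
  if (clean && !has_clean(signal)) {
    rlang::abort("Signal has no clean_* columns.")
  }
  m <- as.matrix(as.data.frame(signal)[, cols])
  colnames(m) <- c("si", "ap", "lr")
  m
}

#' @exportS3Method ggplot2::autoplot
autoplot.resp_signal <- function(object, clean = has_clean(object), ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", axis_cols())],
    cols = -"time_s", names_to = "axis", values_to = "displacement_mm"
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$displacement_mm)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::facet_wrap(~axis, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)",
                  title = attr(object, "signal_id"))
  if (clean && has_clean(object)) {
    dfc <- tidyr::pivot_longer(
      stats::setNames(tibble::as_tibble(object)[, c("time_s", clean_cols())],
                      c("time_s", axis_cols())),
      cols = -"time_s", names_to = "axis", values_to = "displacement_mm"
    )
    p <- p + ggplot2::geom_line(data = dfc, colour = "firebrick",
                                linewidth = 0.3)
  }
  p
}
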