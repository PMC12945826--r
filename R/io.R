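#' Write / read a respiratory signal as delimited text
#'
#' Signal files are plain CSV with header
#' `time_s,si_mm,ap_mm,lr_mm[,clean_si_mm,clean_ap_mm,clean_lr_mm]`;
#' unknown columns are preserved. Numeric values round-trip at full double
#' precision (>= 15 significant digits).
#'
#' @param signal A [resp_signal()].
#' @param path Output file.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns a [resp_signal()].
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "resp_signal"))
  readr::write_csv(tibble::as_tibble(signal), path)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param sampling_rate_hz Sampling rate of the stored signal; by default
#'   inferred from the `time_s` column spacing.
#' @param signal_id Identifier; defaults to the file name.
#' @export
read_signal_csv <- function(path, sampling_rate_hz = NULL, signal_id = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("File not found: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) rlang::abort(paste0("Cannot parse `", path, "`: ",
                                            conditionMessage(e)))
  )
  if (nrow(df) == 0) rlang::abort(paste0("Signal file is empty: ", path))
  required <- c("time_s", "si_mm", "ap_mm", "lr_mm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("Signal file is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in intersect(c(required, clean_cols()), names(df))) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad) > 0) {
      rlang::abort(sprintf("Non-numeric or non-finite value in column `%s` at row %d.",
                           col, bad[1]))
    }
  }
  dt <- diff(df$time_s)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf("Non-monotone `time_s` at row %d.", bad[1] + 1L))
  }
  if (is.null(sampling_rate_hz)) sampling_rate_hz <- 1 / stats::median(dt)
  if (is.null(signal_id)) signal_id <- sub("\\.csv$", "", basename(path))
  resp_signal(df, sampling_rate_hz = sampling_rate_hz, signal_id = signal_id)
}

#' Write / read a motion label sidecar as JSON
#'
#' @param label One-row label tibble (see [label_from_clean()]).
#' @param path Output file.
#' @export
write_label_json <- function(label, path) {
  jsonlite::write_json(as.list(label[1, ]), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_label_json
#' @export
read_label_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(obj)
}

#' Write a simulated dataset to disk
#'
#' One CSV per signal, one JSON label sidecar per signal, plus a
#' `manifest.json` listing (signal path, label path, patient, seed).
#'
#' @param dataset Output of [simulate_breathing()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(seq_len(nrow(dataset)), function(i) {
    sid <- dataset$signal_id[i]
    sig_path <- file.path(dir, paste0(sid, ".csv"))
    lab_path <- file.path(dir, paste0(sid, ".label.json"))
    write_signal_csv(dataset$signal[[i]], sig_path)
    write_label_json(dataset[i, intersect(names(dataset), c(
      "signal_id", "erom_si_mm", "erom_ap_mm", "erom_lr_mm",
      "dominant_amplitude_mm", "motion_class", "representative_value_mm",
      "excessive"))], lab_path)
    tibble::tibble(signal_id = sid, patient_id = dataset$patient_id[i],
                   signal_path = basename(sig_path),
                   label_path = basename(lab_path),
                   seed = dataset$seed[i])
  })
  jsonlite::write_json(rows, file.path(dir, "manifest.json"), digits = NA)
  invisible(rows)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory containing `manifest.json`.
#' @return A tibble like the output of [simulate_breathing()].
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    rlang::abort(paste0("No manifest.json under ", dir))
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  purrr::map_dfr(seq_len(nrow(man)), function(i) {
    sig <- read_signal_csv(file.path(dir, man$signal_path[i]),
                           signal_id = man$signal_id[i])
    lab <- read_label_json(file.path(dir, man$label_path[i]))
    dplyr::bind_cols(
      tibble::tibble(signal_id = man$signal_id[i],
                     patient_id = man$patient_id[i], seed = man$seed[i]),
      lab[, setdiff(names(lab), "signal_id")],
      tibble::tibble(signal = list(sig))
    )
  })
}

#' Write an evaluation report (JSON) and residual dump (CSV)
#'
#' @param report An `evaluation_report`.
#' @param path Output JSON file.
#' @param residuals_path Optional CSV path for the per-window residuals.
#' @export
write_report_json <- function(report, path, residuals_path = NULL) {
  obj <- list(
    schema = report$meta$schema,
    summary = report$summary,
    per_class = report$per_class,
    rmse_table = report$rmse_table,
    rmse_by_latency = report$rmse_by_latency,
    recon_mae = report$recon_mae,
    excessive = report$excessive,
    confusion = unclass(report$confusion)
  )
  jsonlite::write_json(obj, path, digits = NA)
  if (!is.null(residuals_path) && !is.null(report$residuals)) {
    readr::write_csv(report$residuals, residuals_path)
  }
  invisible(path)
}
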