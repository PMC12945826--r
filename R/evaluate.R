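#' Confusion matrix for motion-range classification
#'
#' @param truth Integer true classes (1..n_classes).
#' @param estimate Integer predicted classes.
#' @param n_classes Number of classes (default 4).
#' @return An `n x n` integer matrix of class `motion_confusion`; rows are
#'   the true class, columns the predicted class.
#' @export
confusion_matrix <- function(truth, estimate, n_classes = 4) {
  if (length(truth) != length(estimate)) {
    rlang::abort("`truth` and `estimate` must have equal length.")
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 1:n_classes, predicted = 1:n_classes))
  for (i in seq_along(truth)) {
    cm[truth[i], estimate[i]] <- cm[truth[i], estimate[i]] + 1L
  }
  structure(cm, class = c("motion_confusion", "matrix", "array"))
}

#' @exportS3Method ggplot2::autoplot
autoplot.motion_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class")
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`; a 0/0 ratio is
#' defined as 0 and flagged degenerate.
#'
#' @param cm A confusion matrix (rows true, columns predicted) with
#'   non-negative counts.
#' @return A tibble with one row per class: `class`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(cm) {
  cm <- unclass(cm)
  if (any(cm < 0)) rlang::abort("Confusion-matrix counts must be non-negative.")
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  tibble::tibble(
    class = seq_len(k), tp = as.integer(unname(tp)),
    fp = as.integer(unname(fp)), fn = as.integer(unname(fn)),
    precision = unname(precision), recall = unname(recall),
    f1 = unname(f1),
    degenerate = unname((tp + fp == 0) | (tp + fn == 0) |
                          (precision + recall == 0))
  )
}

#' Classification accuracy from a confusion matrix
#' @param cm A confusion matrix.
#' @return Fraction of correctly classified examples.
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  sum(diag(cm)) / sum(cm)
}

#' One-vs-rest ROC AUC per class
#'
#' AUC via the Mann-Whitney rank statistic (equivalent to trapezoidal
#' integration of the ROC curve), with tied scores averaged. A class with
#' no positive or no negative examples has undefined AUC, reported as `NA`.
#'
#' @param scores Matrix `[n x n_classes]` of class scores or probabilities.
#' @param labels Integer true classes (1..n_classes).
#' @return A tibble with `class`, `n_pos`, `n_neg`, `auc`.
#' @export
roc_auc_ovr <- function(scores, labels) {
  if (nrow(scores) != length(labels)) {
    rlang::abort("`scores` rows and `labels` length must agree.")
  }
  k <- ncol(scores)
  purrr::map_dfr(seq_len(k), function(cls) {
    pos <- labels == cls
    n1 <- sum(pos)
    n0 <- sum(!pos)
    auc <- if (n1 == 0 || n0 == 0) {
      NA_real_
    } else {
      r <- rank(scores[, cls], ties.method = "average")
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }
    tibble::tibble(class = cls, n_pos = n1, n_neg = n0, auc = auc)
  })
}

#' Root-mean-square error
#' @param pred,truth Numeric arrays of identical shape.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (!all(dim2(pred) == dim2(truth))) rlang::abort("Shapes of `pred` and `truth` disagree.")
  sqrt(mean((pred - truth)^2))
}

#' Mean absolute error
#' @param pred,truth Numeric arrays of identical shape.
#' @return `mean(abs(pred - truth))`.
#' @export
mae <- function(pred, truth) {
  if (!all(dim2(pred) == dim2(truth))) rlang::abort("Shapes of `pred` and `truth` disagree.")
  mean(abs(pred - truth))
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(max_value^2 / MSE)` in decibels; identical inputs
#' (MSE 0) are reported as `Inf` with attribute `infinite = TRUE`.
#'
#' @param reference,test Numeric arrays of identical shape.
#' @param max_value Peak signal value (positive).
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, max_value = 1) {
  if (!all(dim2(reference) == dim2(test))) {
    rlang::abort("Shapes of `reference` and `test` disagree.")
  }
  if (max_value <= 0) rlang::abort("`max_value` must be positive.")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(structure(Inf, infinite = TRUE))
  10 * log10(max_value^2 / mse)
}

#' Reference predictors for the latency sweep
#'
#' Simple baselines for Table-style comparisons: `"persistence"` forecasts
#' every horizon as the last observed value; `"linear_extrapolation"` fits
#' the last two samples and extrapolates linearly.
#'
#' @param name `"persistence"` or `"linear_extrapolation"`.
#' @return A function taking a `windowed_dataset` and returning a
#'   `[n_windows x 3 * n_horizons]` matrix of predicted normalized
#'   positions in the same layout as the dataset's `reg_targets`.
#' @export
reference_predictor <- function(name = c("persistence", "linear_extrapolation")) {
  name <- match.arg(name)
  function(windows) {
    w <- windows$spec$window_len_samples
    hz <- windows$spec$horizons_samples
    x_last <- windows$inputs[, w, , drop = FALSE]
    dim(x_last) <- dim(windows$inputs)[c(1, 3)]
    n <- nrow(x_last)
    out <- matrix(0, n, 3 * length(hz))
    if (name == "persistence") {
      for (hi in seq_along(hz)) out[, (hi - 1) * 3 + 1:3] <- x_last
    } else {
      x_prev <- windows$inputs[, w - 1, , drop = FALSE]
      dim(x_prev) <- dim(x_last)
      slope <- x_last - x_prev
      for (hi in seq_along(hz)) {
        out[, (hi - 1) * 3 + 1:3] <- x_last + hz[hi] * slope
      }
    }
    out
  }
}

#' Per-axis, per-horizon RMSE table of regression predictions
#'
#' @param reg_pred Matrix `[n x 3 * n_horizons]`, horizon-major.
#' @param reg_targets Matrix of identical shape (normalized clean-trace
#'   future positions).
#' @param spec The [window_spec()] naming the horizons.
#' @return A tibble: `horizon_samples`, `latency_ms`, `axis`, `rmse`.
#' @export
regression_rmse_table <- function(reg_pred, reg_targets, spec) {
  if (!all(dim(reg_pred) == dim(reg_targets))) {
    rlang::abort("Shapes of predictions and targets disagree.")
  }
  axes <- c("si", "ap", "lr")
  purrr::map_dfr(seq_along(spec$horizons_samples), function(hi) {
    purrr::map_dfr(1:3, function(a) {
      col <- (hi - 1) * 3 + a
      tibble::tibble(
        horizon_samples = spec$horizons_samples[hi],
        latency_ms = spec$horizon_labels_ms[hi],
        axis = axes[a],
        rmse = rmse(reg_pred[, col], reg_targets[, col])
      )
    })
  })
}

#' Full evaluation of a trained model across latency horizons
#'
#' The complete evaluation protocol on a held-out window set: window-level
#' confusion matrix, accuracy, per-class precision/recall/F1 and
#' one-vs-rest AUC; per-axis and axis-averaged RMSE of the predicted future
#' position at every latency horizon (normalized units, against the clean
#' trace); reconstruction MAE per latency bin (the reconstruction target is
#' the clean input window, so the per-bin values coincide); and
#' excessive-motion precision/recall at probability threshold 0.5.
#'
#' @param fit A `motion_net_fit`.
#' @param windows A non-empty `windowed_dataset` of test examples.
#' @param keep_residuals Store per-window residuals (for aggregation
#'   checks and residual dumps).
#' @return An object of class `evaluation_report`: a list of tibbles
#'   (`summary`, `per_class`, `rmse_table`, `rmse_by_latency`,
#'   `recon_mae`, `excessive`, `confusion`) plus `meta`.
#' @export
latency_sweep <- function(fit, windows, keep_residuals = FALSE) {
  stopifnot(inherits(fit, "motion_net_fit"))
  if (n_windows(windows) == 0) rlang::abort("Empty test set.")
  preds <- predict(fit, windows)
  spec <- windows$spec
  probs <- as.matrix(preds[, paste0(".prob_", 1:4)])

  truth <- windows$meta$motion_class
  cm <- confusion_matrix(truth, preds$.pred_class)
  prf <- precision_recall_f1(cm)
  aucs <- roc_auc_ovr(probs, truth)
  per_class <- dplyr::left_join(prf, aucs[, c("class", "auc")], by = "class")

  hz <- spec$horizons_samples
  reg_pred <- as.matrix(preds[, paste0("pred_h", rep(hz, each = 3), "_",
                                       rep(c("si", "ap", "lr"), length(hz)))])
  rmse_tab <- regression_rmse_table(reg_pred, windows$reg_targets, spec)
  rmse_lat <- dplyr::summarise(
    dplyr::group_by(rmse_tab, .data$horizon_samples, .data$latency_ms),
    rmse_all_axes = mean(.data$rmse), .groups = "drop"
  )

  recon <- attr(preds, "recon")
  recon_mae_value <- mae(recon, windows$recon_targets)
  recon_tab <- tibble::tibble(
    horizon_samples = hz, latency_ms = spec$horizon_labels_ms,
    recon_mae = recon_mae_value
  )

  exc_pred <- preds$excessive_prob > 0.5
  exc_truth <- windows$meta$excessive
  exc_cm <- table(factor(exc_truth, c(FALSE, TRUE)),
                  factor(exc_pred, c(FALSE, TRUE)))
  exc_tp <- exc_cm[2, 2]; exc_fp <- exc_cm[1, 2]; exc_fn <- exc_cm[2, 1]
  excessive <- tibble::tibble(
    tp = as.integer(exc_tp), fp = as.integer(exc_fp), fn = as.integer(exc_fn),
    precision = if (exc_tp + exc_fp == 0) 0 else exc_tp / (exc_tp + exc_fp),
    recall = if (exc_tp + exc_fn == 0) 0 else exc_tp / (exc_tp + exc_fn)
  )

  out <- structure(list(
    summary = tibble::tibble(
      n_windows = n_windows(windows),
      accuracy = accuracy(cm),
      macro_f1 = mean(per_class$f1),
      recon_mae = recon_mae_value
    ),
    per_class = per_class,
    rmse_table = rmse_tab,
    rmse_by_latency = rmse_lat,
    recon_mae = recon_tab,
    excessive = excessive,
    confusion = cm,
    meta = list(
      schema = "respmotion-evaluation-v1",
      tie_break = "lower class index",
      n_horizons = length(hz)
    )
  ), class = "evaluation_report")
  if (keep_residuals) {
    out$residuals <- tibble::tibble(
      window = seq_len(nrow(reg_pred)),
      signal_id = windows$meta$signal_id
    )
    for (hi in seq_along(hz)) {
      for (a in 1:3) {
        col <- (hi - 1) * 3 + a
        out$residuals[[paste0("res_h", hz[hi], "_", c("si", "ap", "lr")[a])]] <-
          reg_pred[, col] - windows$reg_targets[, col]
      }
    }
    out$residuals$abs_recon_err <- rowMeans(abs(recon - windows$recon_targets))
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Motion-estimation evaluation report\n")
  cat(sprintf("  windows: %d | accuracy: %.4f | reconstruction MAE: %.5f\n",
              x$summary$n_windows, x$summary$accuracy, x$summary$recon_mae))
  cat("  per-class F1:",
      paste(sprintf("%d: %.4f", x$per_class$class, x$per_class$f1),
            collapse = "  "), "\n")
  cat("  RMSE by latency bin (all axes):\n")
  for (i in seq_len(nrow(x$rmse_by_latency))) {
    cat(sprintf("    %-8s ms  %.5f\n", x$rmse_by_latency$latency_ms[i],
                x$rmse_by_latency$rmse_all_axes[i]))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.evaluation_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(metric = "accuracy", class = NA_integer_,
                   latency_ms = NA_character_, axis = NA_character_,
                   value = x$summary$accuracy),
    tibble::tibble(metric = "f1", class = x$per_class$class,
                   latency_ms = NA_character_, axis = NA_character_,
                   value = x$per_class$f1),
    tibble::tibble(metric = "auc", class = x$per_class$class,
                   latency_ms = NA_character_, axis = NA_character_,
                   value = x$per_class$auc),
    tibble::tibble(metric = "rmse", class = NA_integer_,
                   latency_ms = x$rmse_table$latency_ms,
                   axis = x$rmse_table$axis, value = x$rmse_table$rmse),
    tibble::tibble(metric = "recon_mae", class = NA_integer_,
                   latency_ms = x$recon_mae$latency_ms, axis = NA_character_,
                   value = x$recon_mae$recon_mae)
  )
}

#' @exportS3Method generics::glance
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    n_windows = x$summary$n_windows,
    accuracy = x$summary$accuracy,
    macro_f1 = x$summary$macro_f1,
    rmse_shortest = x$rmse_by_latency$rmse_all_axes[1],
    rmse_longest = x$rmse_by_latency$rmse_all_axes[nrow(x$rmse_by_latency)],
    recon_mae = x$summary$recon_mae
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.evaluation_report <- function(object, ...) {
  df <- object$rmse_table
  df$latency_ms <- factor(df$latency_ms, unique(df$latency_ms))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency_ms, y = .data$rmse,
                                   group = .data$axis, colour = .data$axis)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "latency bin (ms)", y = "RMSE (normalized)",
                  colour = "axis")
}
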