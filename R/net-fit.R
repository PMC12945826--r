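#' Configuration of the motion-estimation network
#'
#' The hybrid architecture comprises a stack of dilated causal 1-D
#' convolutions (each followed by layer normalization, ReLU and spatial
#' channel-wise dropout), a single-layer bidirectional LSTM whose two final
#' hidden states form the trunk summary, an autoencoder bottleneck
#' (tanh encoder to a low-dimensional latent code, tanh-hidden decoder
#' reconstructing the clean window), and four task heads: 4-way softmax
#' motion-range classification, future-position regression (one output per
#' axis per horizon, parameterized as a residual added to the window's last
#' observed sample), window reconstruction, and a sigmoid excessive-motion
#' flag. The default sizes are the smallest stack whose receptive field
#' (`1 + (kernel_size - 1) * sum(dilations)` = 31 samples, about 1.5 s at
#' 20 Hz) spans half a breathing cycle.
#'
#' @param window_len Input window length in samples (default 120).
#' @param n_axes Number of motion axes (fixed at 3: SI, AP, LR).
#' @param kernel_size Convolution kernel size (default 3).
#' @param channels Convolution channels (default 32).
#' @param dilations Dilation schedule (default `c(1, 2, 4, 8)`).
#' @param hidden_size LSTM hidden size per direction (default 64).
#' @param latent_dim Autoencoder latent dimension (default 16); must be
#'   smaller than the flattened window dimension.
#' @param decoder_hidden Decoder hidden width (default 128).
#' @param n_horizons Number of prediction horizons (default 4).
#' @param dropout Spatial dropout rate (default 0.2).
#' @param loss_weights Named weights of the composite loss
#'   (classification cross-entropy, regression MSE, reconstruction MAE,
#'   excessive BCE). The defaults `c(2, 100, 20, 1)` compensate for the
#'   very different natural scales of the four terms (cross-entropy is
#'   O(1) while the squared error of normalized positions is O(1e-4)), so
#'   that every head contributes usefully to the shared trunk's gradient.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param lr_decay Optional multiplicative per-epoch learning-rate decay
#'   (default 1, i.e. a constant rate).
#' @param batch_size Minibatch size (default 64).
#' @param epochs Maximum epochs (default 20).
#' @param patience Early-stopping patience on validation loss (default 5).
#' @param seed Seed for parameter initialization, shuffling and dropout.
#' @return A list of class `motion_net_config`.
#' @export
motion_net_config <- function(window_len = 120, n_axes = 3, kernel_size = 3,
                              channels = 32, dilations = c(1, 2, 4, 8),
                              hidden_size = 64, latent_dim = 16,
                              decoder_hidden = 128, n_horizons = 4,
                              dropout = 0.2,
                              loss_weights = c(cls = 2, reg = 100, rec = 20, exc = 1),
                              learning_rate = 1e-3, lr_decay = 1,
                              batch_size = 64,
                              epochs = 20, patience = 5, seed = 1L) {
  if (any(loss_weights < 0) || all(loss_weights == 0)) {
    rlang::abort("`loss_weights` must be non-negative with at least one positive.")
  }
  if (latent_dim >= window_len * n_axes) {
    rlang::abort("`latent_dim` must be smaller than the flattened window (not a compression).")
  }
  if (any(dilations < 1)) rlang::abort("Dilations must be >= 1.")
  structure(list(
    window_len = as.integer(window_len), n_axes = as.integer(n_axes),
    kernel_size = as.integer(kernel_size), channels = as.integer(channels),
    dilations = as.integer(dilations), hidden_size = as.integer(hidden_size),
    latent_dim = as.integer(latent_dim),
    decoder_hidden = as.integer(decoder_hidden),
    n_horizons = as.integer(n_horizons),
    n_reg = as.integer(n_axes * n_horizons),
    recon_dim = as.integer(window_len * n_axes),
    dropout = dropout,
    loss_weights = as.numeric(loss_weights),
    learning_rate = learning_rate, lr_decay = lr_decay,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), patience = as.integer(patience),
    seed = as.integer(seed)
  ), class = "motion_net_config")
}

#' Receptive field of the dilated convolution stack
#'
#' Closed form `1 + (kernel_size - 1) * sum(dilations)`.
#'
#' @param config A [motion_net_config()].
#' @return Receptive field in samples.
#' @export
receptive_field <- function(config) {
  1L + (config$kernel_size - 1L) * sum(config$dilations)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize network parameters
#'
#' Glorot-uniform weight initialization; LSTM forget-gate biases start at 1.
#'
#' @param config A [motion_net_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Named list of parameter matrices.
#' @export
init_motion_net <- function(config, seed = config$seed) {
  withr::with_seed(as.integer(seed), {
    p <- list()
    cin <- config$n_axes
    for (l in seq_along(config$dilations)) {
      p[[paste0("conv_W", l)]] <- glorot(cin * config$kernel_size, config$channels)
      p[[paste0("conv_b", l)]] <- matrix(0, 1, config$channels)
      p[[paste0("ln_g", l)]] <- matrix(1, 1, config$channels)
      p[[paste0("ln_b", l)]] <- matrix(0, 1, config$channels)
      cin <- config$channels
    }
    h <- config$hidden_size
    for (dir in c("f", "b")) {
      bias <- matrix(0, 1, 4 * h)
      bias[1, (h + 1):(2 * h)] <- 1   # forget gate bias
      p[[paste0("lstm_", dir, "_Wx")]] <- glorot(config$channels, 4 * h)
      p[[paste0("lstm_", dir, "_Wh")]] <- glorot(h, 4 * h)
      p[[paste0("lstm_", dir, "_b")]] <- bias
    }
    # heads read the trunk summary augmented with scaled per-axis window
    # amplitude statistics; the rows acting on those statistics (and on the
    # regression head's sample/slope features) start at zero so that the
    # initial forward pass is driven purely by the recurrent trunk
    nstat <- 2 * config$n_axes
    trunk <- 2 * h + nstat
    zero_tail <- function(W, k) { W[seq(nrow(W) - k + 1, nrow(W)), ] <- 0; W }
    p$enc_W <- zero_tail(glorot(trunk, config$latent_dim), nstat)
    p$enc_b <- matrix(0, 1, config$latent_dim)
    p$cls_W <- zero_tail(glorot(trunk, 4), nstat)
    p$cls_b <- matrix(0, 1, 4)
    p$reg_W <- zero_tail(glorot(trunk + 3 * config$n_axes, config$n_reg),
                         nstat + 3 * config$n_axes)
    p$reg_b <- matrix(0, 1, config$n_reg)
    p$exc_W <- zero_tail(glorot(trunk, 1), nstat)
    p$exc_b <- matrix(0, 1, 1)
    p$dec_W1 <- glorot(config$latent_dim, config$decoder_hidden)
    p$dec_b1 <- matrix(0, 1, config$decoder_hidden)
    p$dec_W2 <- glorot(config$decoder_hidden, config$recon_dim)
    p$dec_b2 <- matrix(0, 1, config$recon_dim)
    p
  })
}

window_targets <- function(windows) {
  list(
    ycls = as.integer(windows$meta$motion_class) - 1L,
    yreg = windows$reg_targets,
    yrec = windows$recon_targets,
    yexc = as.numeric(windows$meta$excessive)
  )
}

empty_cube <- function(config) {
  array(0, dim = c(0, config$window_len, config$n_axes))
}

#' Fit the motion-estimation network
#'
#' Joint training of all four heads by minibatch Adam on the composite loss
#' `lw_cls * CE + lw_reg * MSE + lw_rec * MAE + lw_exc * BCE`, with early
#' stopping on the validation composite loss (the parameters of the best
#' validation epoch are retained). Identical `(data, config)` runs are
#' bit-reproducible: parameter initialization, shuffling and dropout all
#' derive from `config$seed`.
#'
#' @param windows A `windowed_dataset` of training examples (see
#'   [make_windows()], [prepare_windows()]).
#' @param config A [motion_net_config()].
#' @param val_windows Optional `windowed_dataset` used for early stopping;
#'   without it, training runs all epochs and keeps the final parameters.
#' @param verbose Print per-epoch losses.
#' @return An object of class `motion_net_fit` with elements `params`,
#'   `config`, `history` (tibble: epoch, train_loss, val_loss),
#'   `best_epoch`, `stopped_early`.
#' @export
fit_motion_net <- function(windows, config = motion_net_config(),
                           val_windows = NULL, verbose = FALSE) {
  stopifnot(inherits(windows, "windowed_dataset"))
  if (n_windows(windows) == 0) rlang::abort("Training dataset is empty.")
  if (dim(windows$inputs)[2] != config$window_len) {
    rlang::abort("Window length of data and config disagree.")
  }
  nh <- length(windows$spec$horizons_samples)
  if (nh != config$n_horizons) {
    rlang::abort("`n_horizons` of data and config disagree.")
  }
  config$horizons <- as.integer(windows$spec$horizons_samples)
  tg <- window_targets(windows)
  if (is.null(val_windows)) {
    vx <- empty_cube(config)
    vt <- list(ycls = integer(0), yreg = matrix(0, 0, config$n_reg),
               yrec = matrix(0, 0, config$recon_dim), yexc = numeric(0))
  } else {
    vx <- val_windows$inputs
    vt <- window_targets(val_windows)
  }
  params <- init_motion_net(config)
  res <- cpp_net_train(params, windows$inputs, tg$ycls, tg$yreg, tg$yrec,
                       tg$yexc, vx, vt$ycls, vt$yreg, vt$yrec, vt$yexc,
                       cpp_config(config), config$epochs, config$batch_size,
                       config$learning_rate, config$lr_decay %||% 1,
                       config$patience, config$seed, verbose)
  structure(list(
    params = res$params,
    config = config,
    history = tibble::tibble(
      epoch = seq_along(res$train_loss),
      train_loss = as.numeric(res$train_loss),
      val_loss = as.numeric(res$val_loss)
    ),
    best_epoch = res$best_epoch,
    stopped_early = res$stopped_early
  ), class = "motion_net_fit")
}

cpp_config <- function(config, horizons = NULL) {
  out <- config[c("window_len", "n_axes", "kernel_size", "channels",
                  "dilations", "hidden_size", "latent_dim", "decoder_hidden",
                  "n_reg", "recon_dim", "loss_weights", "dropout")]
  out$horizons <- as.integer(horizons %||% config$horizons %||%
                               c(1, 3, 6, 10)[seq_len(config$n_horizons)])
  out
}

#' @export
print.motion_net_fit <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<motion_net_fit: %d parameters, %d epoch(s), best epoch %d%s>\n",
              np, nrow(x$history), x$best_epoch,
              if (isTRUE(x$stopped_early)) ", early-stopped" else ""))
  invisible(x)
}

#' Network outputs for a set of windows
#'
#' Runs the trained (or freshly initialized) network on every window and
#' returns the four head outputs. Class probabilities are non-negative and
#' sum to one; the predicted class is the argmax with ties broken toward
#' the lower class (the conservative motion estimate).
#'
#' @param object A `motion_net_fit`.
#' @param windows A `windowed_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per window: `signal_id`, `window_start`,
#'   class probabilities `.prob_1 ... .prob_4`, `.pred_class`,
#'   `excessive_prob`, and the predicted normalized future position
#'   `pred_h{horizon}_{axis}` for every horizon and axis. The decoder
#'   reconstruction is attached as attribute `recon`
#'   (`[n_windows x window_len * 3]`) and the latent codes as `latent`.
#' @export
predict.motion_net_fit <- function(object, windows, ...) {
  stopifnot(inherits(windows, "windowed_dataset"))
  out <- cpp_net_forward(object$params, windows$inputs,
                         cpp_config(object$config))
  probs <- out$class_probs
  colnames(probs) <- paste0(".prob_", 1:4)
  pred_class <- apply(probs, 1, which.max)   # which.max takes the first max
  reg <- out$reg_pred
  hz <- windows$spec$horizons_samples
  colnames(reg) <- paste0("pred_h", rep(hz, each = 3), "_",
                          rep(c("si", "ap", "lr"), length(hz)))
  res <- dplyr::bind_cols(
    windows$meta[, c("signal_id", "window_start")],
    tibble::as_tibble(probs),
    tibble::tibble(.pred_class = as.integer(pred_class),
                   excessive_prob = as.numeric(out$excessive_prob)),
    tibble::as_tibble(reg)
  )
  attr(res, "recon") <- out$recon
  attr(res, "latent") <- out$z
  res
}

#' @exportS3Method generics::tidy
tidy.motion_net_fit <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    rows = vapply(x$params, nrow, integer(1)),
    cols = vapply(x$params, ncol, integer(1)),
    n = vapply(x$params, length, integer(1)),
    mean = vapply(x$params, mean, numeric(1)),
    sd = vapply(x$params, stats::sd, numeric(1))
  )
}

#' @exportS3Method generics::glance
glance.motion_net_fit <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs_run = nrow(x$history),
    best_epoch = x$best_epoch,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    best_val_loss = if (all(is.na(x$history$val_loss))) NA_real_ else
      min(x$history$val_loss, na.rm = TRUE),
    stopped_early = isTRUE(x$stopped_early),
    receptive_field = receptive_field(x$config)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.motion_net_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "loss")
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "composite loss", colour = NULL)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file embedding the configuration and all
#' parameter matrices at full double precision, so a reloaded model
#' reproduces inference bit for bit on the same platform.
#'
#' @param fit A `motion_net_fit`.
#' @param path Output file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `motion_net_fit`.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "motion_net_fit"))
  obj <- list(
    format = "respmotion-checkpoint-v1",
    config = unclass(fit$config),
    # doubles are stored as %.17g strings, which round-trip IEEE doubles
    # exactly (plain JSON numbers lose the last ulp)
    params = lapply(fit$params, function(m) {
      list(dim = dim(m), data = sprintf("%.17g", as.numeric(m)))
    }),
    history = fit$history,
    best_epoch = fit$best_epoch,
    stopped_early = fit$stopped_early
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "respmotion-checkpoint-v1")) {
    rlang::abort("Not a respmotion checkpoint file.")
  }
  cfg <- obj$config
  config <- motion_net_config(
    window_len = cfg$window_len, n_axes = cfg$n_axes,
    kernel_size = cfg$kernel_size, channels = cfg$channels,
    dilations = cfg$dilations, hidden_size = cfg$hidden_size,
    latent_dim = cfg$latent_dim, decoder_hidden = cfg$decoder_hidden,
    n_horizons = cfg$n_horizons, dropout = cfg$dropout,
    loss_weights = cfg$loss_weights, learning_rate = cfg$learning_rate,
    lr_decay = cfg$lr_decay %||% 1, batch_size = cfg$batch_size,
    epochs = cfg$epochs, patience = cfg$patience, seed = cfg$seed
  )
  config$horizons <- cfg$horizons
  params <- lapply(obj$params, function(p) {
    matrix(as.numeric(p$data), p$dim[1], p$dim[2])
  })
  structure(list(
    params = params, config = config,
    history = tibble::as_tibble(obj$history),
    best_epoch = obj$best_epoch, stopped_early = obj$stopped_early
  ), class = "motion_net_fit")
}
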