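#' Dilated causal 1-D convolution
#'
#' Computes `out[p] = sum_i x[p - d*(i-1)] * kernel[i]` with out-of-range
#' terms treated as zero (causal left zero-padding), so the output has the
#' input's length. With `dilation = 1` this is the standard discrete
#' convolution; larger dilations space the kernel taps `d` samples apart,
#' widening the receptive field without extra parameters.
#'
#' @param x Numeric input sequence (non-empty).
#' @param kernel Numeric kernel (non-empty); `kernel[1]` multiplies the
#'   current sample, later taps reach back in time.
#' @param dilation Positive integer dilation factor.
#' @return Numeric vector of `length(x)`.
#' @export
#' @examples
#' dilated_conv1d(c(1, 2, 3, 4, 5), c(1, 1, 1), dilation = 2)
dilated_conv1d <- function(x, kernel, dilation = 1) {
  if (length(x) == 0 || length(kernel) == 0) {
    rlang::abort("`x` and `kernel` must be non-empty.")
  }
  if (dilation < 1 || dilation != round(dilation)) {
    rlang::abort("`dilation` must be a positive integer.")
  }
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(kernel)) {
    lag <- dilation * (i - 1)
    if (lag >= n) break
    out[(lag + 1):n] <- out[(lag + 1):n] + kernel[i] * x[1:(n - lag)]
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Single-direction LSTM pass (reference implementation)
#'
#' Standard LSTM gate algebra: input, forget and output gates (sigmoid),
#' candidate cell (tanh), `c_t = f * c_{t-1} + i * g`, `h_t = o * tanh(c_t)`.
#' Used as the plain-R reference against which the C++ training engine is
#' cross-checked.
#'
#' @param X Numeric matrix `[T x D]`, one feature row per time step.
#' @param Wx `[D x 4H]` input weights (gate order: input, forget, cell,
#'   output).
#' @param Wh `[H x 4H]` recurrent weights.
#' @param b Length-`4H` bias.
#' @return Matrix `[T x H]` of hidden states.
#' @export
lstm_forward <- function(X, Wx, Wh, b) {
  T_ <- nrow(X)
  H <- nrow(Wh)
  if (ncol(X) != nrow(Wx) || ncol(Wx) != 4 * H || length(b) != 4 * H) {
    rlang::abort("LSTM parameter dimensions disagree with the input features.")
  }
  h <- numeric(H)
  cc <- numeric(H)
  out <- matrix(0, T_, H)
  for (t in seq_len(T_)) {
    a <- drop(X[t, ] %*% Wx) + drop(h %*% Wh) + b
    gi <- sigmoid(a[1:H])
    gf <- sigmoid(a[(H + 1):(2 * H)])
    gg <- tanh(a[(2 * H + 1):(3 * H)])
    go <- sigmoid(a[(3 * H + 1):(4 * H)])
    cc <- gf * cc + gi * gg
    h <- go * tanh(cc)
    out[t, ] <- h
  }
  out
}

#' Bidirectional LSTM pass (reference implementation)
#'
#' Runs a forward stream over `x_1..x_T` and a backward stream over the
#' reversed sequence; the per-step output `y_t` is the concatenation of the
#' forward hidden state at `t` and the backward hidden state at `t`, so the
#' feature dimension is `2H` at every step. The forward half depends only
#' on `x_1..x_t`, the backward half only on `x_t..x_T`.
#'
#' @param X Numeric matrix `[T x D]` (non-empty).
#' @param params List with elements `f` and `b`, each a list of `Wx`, `Wh`,
#'   `b` as in [lstm_forward()].
#' @return Matrix `[T x 2H]`.
#' @export
bilstm_forward <- function(X, params) {
  if (!is.matrix(X) || nrow(X) == 0) rlang::abort("`X` must be a non-empty matrix.")
  fwd <- lstm_forward(X, params$f$Wx, params$f$Wh, params$f$b)
  bwd <- lstm_forward(X[rev(seq_len(nrow(X))), , drop = FALSE],
                      params$b$Wx, params$b$Wh, params$b$b)
  cbind(fwd, bwd[rev(seq_len(nrow(X))), , drop = FALSE])
}

#' Extract the BiLSTM parameters of a fit as a reference-parameter list
#'
#' @param fit A `motion_net_fit`.
#' @return A list usable as the `params` argument of [bilstm_forward()].
#' @export
bilstm_params <- function(fit) {
  p <- fit$params
  list(
    f = list(Wx = p$lstm_f_Wx, Wh = p$lstm_f_Wh, b = drop(p$lstm_f_b)),
    b = list(Wx = p$lstm_b_Wx, Wh = p$lstm_b_Wh, b = drop(p$lstm_b_b))
  )
}

#' Encode windows into latent codes / decode latent codes into windows
#'
#' The encoder maps the conv + BiLSTM trunk summary of each window to a
#' latent code `z = tanh(W u + b)` of dimension `latent_dim`; the decoder
#' reconstructs the flattened window from `z`. `decode(encode(x))` always
#' has the shape of `x`.
#'
#' @param fit A `motion_net_fit`.
#' @param windows A `windowed_dataset`.
#' @return `model_encode`: matrix `[n_windows x latent_dim]` of latent
#'   codes. `model_decode`: array `[n_codes x window_len x 3]` of
#'   reconstructed windows.
#' @export
model_encode <- function(fit, windows) {
  out <- cpp_net_forward(fit$params, windows$inputs, cpp_config(fit$config))
  out$z
}

#' @rdname model_encode
#' @param z Matrix of latent codes `[n x latent_dim]`.
#' @export
model_decode <- function(fit, z) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != fit$config$latent_dim) {
    rlang::abort("`z` must have `latent_dim` columns.")
  }
  d1 <- tanh(z %*% fit$params$dec_W1 +
               matrix(fit$params$dec_b1, nrow(z), fit$config$decoder_hidden,
                      byrow = TRUE))
  flat <- d1 %*% fit$params$dec_W2 +
    matrix(fit$params$dec_b2, nrow(z), fit$config$recon_dim, byrow = TRUE)
  array(flat, dim = c(nrow(z), fit$config$window_len, fit$config$n_axes))
}

#' Composite multi-task loss (reference implementation)
#'
#' `loss = lw_cls * CE(class) + lw_reg * MSE(positions) +
#'  lw_rec * MAE(reconstruction) + lw_exc * BCE(excessive)`; non-negative,
#' and zero exactly when every head is perfect (probability one on the true
#' class, exact positions and reconstruction, excessive probability in
#' {0, 1} matching the truth).
#'
#' @param predictions List with `class_probs` (matrix `[n x 4]`),
#'   `reg_pred`, `recon`, `excessive_prob`.
#' @param targets List with `motion_class` (integer 1-4), `reg`, `recon`,
#'   `excessive` (logical or 0/1).
#' @param weights Four non-negative weights (cls, reg, rec, exc).
#' @return Scalar loss, with the four components as attribute
#'   `"components"`.
#' @export
composite_loss <- function(predictions, targets,
                           weights = c(cls = 1, reg = 1, rec = 1, exc = 1)) {
  if (any(weights < 0)) rlang::abort("Loss weights must be non-negative.")
  probs <- predictions$class_probs
  n <- nrow(probs)
  stopifnot(nrow(predictions$reg_pred) == n, nrow(predictions$recon) == n)
  if (!all(dim(predictions$reg_pred) == dim(targets$reg)) ||
      !all(dim(predictions$recon) == dim(targets$recon))) {
    rlang::abort("Prediction and target shapes disagree.")
  }
  p_true <- probs[cbind(seq_len(n), targets$motion_class)]
  ce <- mean(-log(pmax(p_true, 1e-12)))
  mse <- mean((predictions$reg_pred - targets$reg)^2)
  mae <- mean(abs(predictions$recon - targets$recon))
  pe <- pmin(pmax(predictions$excessive_prob, 1e-9), 1 - 1e-9)
  ye <- as.numeric(targets$excessive)
  bce <- mean(-(ye * log(pe) + (1 - ye) * log(1 - pe)))
  comp <- c(ce = ce, mse = mse, mae = mae, bce = bce)
  structure(sum(weights * comp), components = comp)
}
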