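test_that("dilated convolution matches hand evaluation and the brute-force oracle", {
  expect_equal(dilated_conv1d(c(1, 2, 3, 4, 5), c(1, 1, 1), 2),
               c(1, 2, 4, 6, 9))
  # identity kernel leaves any input unchanged at any dilation
  withr::with_seed(13, {
    x <- stats::rnorm(50)
    for (d in c(1, 2, 4, 8)) {
      expect_equal(dilated_conv1d(x, c(1, 0, 0), d), x)
    }
    k <- stats::rnorm(3)
    expect_lt(max(abs(dilated_conv1d(x, k, 4) - oracle_dilated_conv(x, k, 4))),
              1e-9)
    # d = 1 recovers the standard discrete (causal) convolution
    std <- as.numeric(stats::filter(x, k, method = "convolution",
                                    sides = 1))
    std[is.na(std)] <- oracle_dilated_conv(x, k, 1)[is.na(std)]
    expect_lt(max(abs(dilated_conv1d(x, k, 1) - std)), 1e-9)
  })
  expect_error(dilated_conv1d(numeric(0), 1), "non-empty")
  expect_error(dilated_conv1d(1:3, numeric(0)), "non-empty")
  expect_error(dilated_conv1d(1:3, 1, dilation = 0), "positive")
})

test_that("the receptive field closed form matches the impulse response", {
  cfg <- motion_net_config()
  x <- c(1, numeric(199))
  y <- x
  for (d in cfg$dilations) y <- dilated_conv1d(y, rep(1, cfg$kernel_size), d)
  expect_equal(sum(y != 0), receptive_field(cfg))
  expect_equal(receptive_field(cfg), 31)
})

test_that("the BiLSTM contract holds: zero params, output width, directionality", {
  withr::with_seed(3, {
    T_ <- 12; D <- 4; H <- 6
    X <- matrix(stats::rnorm(T_ * D), T_, D)
    zero <- list(Wx = matrix(0, D, 4 * H), Wh = matrix(0, H, 4 * H),
                 b = numeric(4 * H))
    Y0 <- bilstm_forward(X, list(f = zero, b = zero))
    expect_equal(dim(Y0), c(T_, 2 * H))
    expect_true(all(Y0 == 0))

    p <- list(
      f = list(Wx = matrix(stats::rnorm(D * 4 * H), D) * 0.3,
               Wh = matrix(stats::rnorm(H * 4 * H), H) * 0.3,
               b = stats::rnorm(4 * H) * 0.1),
      b = list(Wx = matrix(stats::rnorm(D * 4 * H), D) * 0.3,
               Wh = matrix(stats::rnorm(H * 4 * H), H) * 0.3,
               b = stats::rnorm(4 * H) * 0.1)
    )
    Y <- bilstm_forward(X, p)
    expect_equal(dim(Y), c(T_, 2 * H))
    # forward half depends only on x_1..t: perturbing the future leaves it
    X2 <- X; X2[T_, ] <- X2[T_, ] + 1
    Y2 <- bilstm_forward(X2, p)
    expect_equal(Y2[1:(T_ - 1), 1:H], Y[1:(T_ - 1), 1:H])
    # backward half only on x_t..T
    X3 <- X; X3[1, ] <- X3[1, ] + 1
    Y3 <- bilstm_forward(X3, p)
    expect_equal(Y3[2:T_, (H + 1):(2 * H)], Y[2:T_, (H + 1):(2 * H)])
    # the backward half is the forward stream run on the reversed sequence
    Yrev <- lstm_forward(X[T_:1, ], p$b$Wx, p$b$Wh, p$b$b)
    expect_equal(Y[, (H + 1):(2 * H)], Yrev[T_:1, ])
  })
  expect_error(bilstm_forward(matrix(1, 3, 5),
                              list(f = list(Wx = matrix(0, 4, 8),
                                            Wh = matrix(0, 2, 8),
                                            b = numeric(8)))),
               "dimensions")
})

test_that("the C++ trunk agrees with the plain-R conv and BiLSTM references", {
  cfg <- tiny_net_config()
  p <- init_motion_net(cfg, seed = 9)
  withr::with_seed(5, {
    X <- array(stats::runif(2 * 16 * 3), dim = c(2, 16, 3))
  })
  out <- cpp_net_forward(p, X, cpp_config(cfg), return_conv = TRUE)
  layer_norm_ref <- function(Y, g, b) {
    mu <- rowMeans(Y); xc <- Y - mu; v <- rowMeans(xc^2)
    sweep(sweep(xc / sqrt(v + 1e-5), 2, g, "*"), 2, b, "+")
  }
  for (s in 1:2) {
    cur <- X[s, , ]
    for (l in seq_along(cfg$dilations)) {
      W <- p[[paste0("conv_W", l)]]
      cin <- ncol(cur)
      Y <- matrix(0, 16, ncol(W))
      for (o in seq_len(ncol(W))) {
        acc <- numeric(16)
        for (i in seq_len(cfg$kernel_size)) {
          for (ch in seq_len(cin)) {
            kern <- numeric(cfg$kernel_size)
            kern[i] <- W[(i - 1) * cin + ch, o]
            acc <- acc + dilated_conv1d(cur[, ch], kern, cfg$dilations[l])
          }
        }
        Y[, o] <- acc + p[[paste0("conv_b", l)]][1, o]
      }
      cur <- pmax(layer_norm_ref(Y, p[[paste0("ln_g", l)]][1, ],
                                 p[[paste0("ln_b", l)]][1, ]), 0)
    }
    expect_lt(max(abs(out$conv_out[(s - 1) * 16 + 1:16, ] - cur)), 1e-10)
    Yb <- bilstm_forward(cur, list(
      f = list(Wx = p$lstm_f_Wx, Wh = p$lstm_f_Wh, b = drop(p$lstm_f_b)),
      b = list(Wx = p$lstm_b_Wx, Wh = p$lstm_b_Wh, b = drop(p$lstm_b_b))
    ))
    H <- cfg$hidden_size
    expect_lt(max(abs(out$trunk[s, ] - c(Yb[16, 1:H], Yb[1, H + 1:H]))),
              1e-10)
  }
})

test_that("encode/decode respect the bottleneck shape contract", {
  cfg <- motion_net_config()
  p <- init_motion_net(cfg, seed = 2)
  fit <- structure(list(params = p, config = cfg), class = "motion_net_fit")
  sig <- make_sine_signal(260, seed = 3)
  w <- make_windows(sig, label = tibble::tibble(motion_class = 1L,
                                                excessive = FALSE))
  z <- model_encode(fit, w)
  expect_equal(dim(z), c(n_windows(w), 16))
  xhat <- model_decode(fit, z)
  expect_equal(dim(xhat), c(n_windows(w), 120, 3))
  expect_error(model_decode(fit, matrix(0, 1, 5)), "latent_dim")
  # a latent wider than the flattened window is not a compression
  expect_error(motion_net_config(window_len = 4, latent_dim = 12),
               "compression")
})

test_that("softmax outputs normalize and inference is deterministic", {
  cfg <- tiny_net_config()
  p <- init_motion_net(cfg, seed = 4)
  withr::with_seed(8, {
    X <- array(stats::runif(5 * 16 * 3), dim = c(5, 16, 3))
  })
  o1 <- cpp_net_forward(p, X, cpp_config(cfg))
  o2 <- cpp_net_forward(p, X, cpp_config(cfg))
  expect_identical(o1, o2)
  expect_lt(max(abs(rowSums(o1$class_probs) - 1)), 1e-6)
  expect_true(all(o1$class_probs >= 0))
  expect_true(all(o1$excessive_prob >= 0 & o1$excessive_prob <= 1))
})

test_that("the composite loss matches a term-by-term oracle and its contracts", {
  withr::with_seed(2, {
    n <- 5
    probs <- matrix(stats::runif(n * 4), n); probs <- probs / rowSums(probs)
    ycls <- sample(1:4, n, replace = TRUE)
    reg_pred <- matrix(stats::rnorm(n * 6), n)
    yreg <- matrix(stats::rnorm(n * 6), n)
    recon <- matrix(stats::rnorm(n * 24), n)
    yrec <- matrix(stats::rnorm(n * 24), n)
    exc <- stats::runif(n)
    yexc <- as.numeric(stats::runif(n) > 0.5)
    w <- c(0.7, 1.3, 1.0, 0.5)
    got <- composite_loss(
      list(class_probs = probs, reg_pred = reg_pred, recon = recon,
           excessive_prob = exc),
      list(motion_class = ycls, reg = yreg, recon = yrec, excessive = yexc),
      weights = w)
    want <- oracle_composite_loss(probs, ycls, reg_pred, yreg, recon, yrec,
                                  exc, yexc, w)
    expect_lt(abs(as.numeric(got) - want), 1e-9)

    # perfect predictions: zero loss
    perfect_probs <- diag(4)[ycls[1:4], ]
    zero <- composite_loss(
      list(class_probs = perfect_probs, reg_pred = yreg[1:4, ],
           recon = yrec[1:4, ], excessive_prob = yexc[1:4]),
      list(motion_class = ycls[1:4], reg = yreg[1:4, ], recon = yrec[1:4, ],
           excessive = yexc[1:4]))
    expect_lt(as.numeric(zero), 1e-8)

    # weights (0, 0, 1, 0): plain reconstruction MAE
    only_rec <- composite_loss(
      list(class_probs = probs, reg_pred = reg_pred, recon = recon,
           excessive_prob = exc),
      list(motion_class = ycls, reg = yreg, recon = yrec, excessive = yexc),
      weights = c(0, 0, 1, 0))
    expect_equal(as.numeric(only_rec), mean(abs(recon - yrec)))
    expect_error(composite_loss(list(), list(), weights = c(-1, 1, 1, 1)),
                 "non-negative")
  })
})
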