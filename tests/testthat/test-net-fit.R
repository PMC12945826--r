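small_training_set <- function(n_records = 6, stride = 60, seed = 21,
                               amp = c(2, 5, 7, 10)) {
  cfg0 <- generator_config(noise_sd_mm = 0.02)
  parts <- lapply(seq_len(n_records), function(i) {
    rec <- generate_signal(amp[(i - 1) %% length(amp) + 1], cfg0,
                           seed = seed + i,
                           signal_id = sprintf("p%02d_s01", i))
    make_windows(dwt_denoise(rec$signal), rec$label,
                 window_spec(stride = stride))
  })
  bind_windows(parts)
}

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_net_config()
  withr::with_seed(42, {
    n <- 3
    X <- array(stats::runif(n * 16 * 3), dim = c(n, 16, 3))
    ycls <- sample(0:3, n, replace = TRUE)
    yreg <- matrix(stats::runif(n * 6), n)
    yrec <- matrix(stats::runif(n * 48), n)
    yexc <- as.numeric(stats::runif(n) > 0.5)
    p <- init_motion_net(cfg, seed = 9)
    ccfg <- cpp_config(cfg)
    res <- cpp_net_loss_grad(p, X, ycls, yreg, yrec, yexc, ccfg, -1L)
    eps <- 1e-6
    for (nm in names(p)) {
      g <- res$grads[[nm]]
      for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
        pp <- p
        pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- cpp_net_loss_grad(pp, X, ycls, yreg, yrec, yexc, ccfg, -1L)$loss
        pp[[nm]][i] <- pp[[nm]][i] - 2 * eps
        lm <- cpp_net_loss_grad(pp, X, ycls, yreg, yrec, yexc, ccfg, -1L)$loss
        fd <- (lp - lm) / (2 * eps)
        expect_lt(abs(fd - g[i]) / max(1e-6, abs(fd), abs(g[i])), 1e-4)
      }
    }
  })
})

test_that("a one-batch, one-epoch run produces a finite single-entry history", {
  w <- small_training_set(2, stride = 600)
  cfg <- motion_net_config(epochs = 1, batch_size = 64, seed = 1)
  fit <- fit_motion_net(w, cfg)
  expect_equal(nrow(fit$history), 1)
  expect_true(is.finite(fit$history$train_loss))
  expect_error(fit_motion_net(subset_windows(w, integer(0)), cfg), "empty")
})

test_that("training is bit-reproducible under a fixed seed", {
  w <- small_training_set(4, stride = 300)
  cfg <- motion_net_config(epochs = 2, seed = 7)
  f1 <- fit_motion_net(w, cfg)
  f2 <- fit_motion_net(w, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training reduces the loss and the autoencoder learns to reconstruct", {
  w <- small_training_set(6, stride = 120)
  cfg <- motion_net_config(epochs = 5, seed = 1)
  before <- structure(list(params = init_motion_net(cfg), config = cfg),
                      class = "motion_net_fit")
  out0 <- cpp_net_forward(before$params, w$inputs, cpp_config(cfg))
  fit <- fit_motion_net(w, cfg)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
  out1 <- cpp_net_forward(fit$params, w$inputs, cpp_config(cfg))
  expect_lt(mean(abs(out1$recon - w$recon_targets)),
            mean(abs(out0$recon - w$recon_targets)))
})

test_that("early stopping restores the best validation epoch", {
  w <- small_training_set(6, stride = 200)
  sp <- split_patients(w, test_frac = 0.2, val_frac = 0.3, seed = 2)
  cfg <- motion_net_config(epochs = 4, patience = 2, seed = 5)
  fit <- fit_motion_net(subset_windows(w, sp$train), cfg,
                        val_windows = subset_windows(w, sp$val))
  expect_true(fit$best_epoch >= 1)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in%
                    names(fit$history)))
  g <- glance(fit)
  expect_equal(g$epochs_run, nrow(fit$history))
  expect_gt(g$n_parameters, 0)
  td <- tidy(fit)
  expect_true(all(c("parameter", "rows", "cols") %in% names(td)))
})

test_that("checkpoints round-trip bit-exactly", {
  w <- small_training_set(2, stride = 600)
  cfg <- motion_net_config(epochs = 1, seed = 3)
  fit <- fit_motion_net(w, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_identical(fit$params, fit2$params)
  p1 <- predict(fit, w)
  p2 <- predict(fit2, w)
  expect_identical(p1, p2)
  not_ckpt <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), not_ckpt)
  expect_error(load_checkpoint(not_ckpt), "checkpoint")
})

test_that("predict returns tidy per-window output with probabilities and positions", {
  w <- small_training_set(2, stride = 600)
  cfg <- motion_net_config(epochs = 1, seed = 3)
  fit <- fit_motion_net(w, cfg)
  pr <- predict(fit, w)
  expect_s3_class(pr, "tbl_df")
  expect_equal(nrow(pr), n_windows(w))
  expect_true(all(c(".pred_class", ".prob_1", ".prob_4", "excessive_prob",
                    "pred_h1_si", "pred_h10_lr") %in% names(pr)))
  expect_lt(max(abs(rowSums(as.matrix(pr[, paste0(".prob_", 1:4)])) - 1)),
            1e-6)
  expect_equal(dim(attr(pr, "recon")), c(n_windows(w), 360))
})
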