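test_that("precision, recall and F1 follow their defining formulas", {
  # class 1: TP = 9, FP = 1, FN = 1
  cm <- confusion_matrix(c(rep(1, 10), rep(2, 10)),
                         c(rep(1, 9), 2, 1, rep(2, 9)))
  prf <- precision_recall_f1(cm)
  expect_equal(prf$precision[1], 0.9)
  expect_equal(prf$recall[1], 0.9)
  expect_equal(prf$f1[1], 0.9)

  # diagonal-only matrix: perfect scores for every non-empty class
  cmd <- confusion_matrix(c(1, 2, 3, 4, 4), c(1, 2, 3, 4, 4))
  prfd <- precision_recall_f1(cmd)
  expect_true(all(prfd$precision == 1 & prfd$recall == 1 & prfd$f1 == 1))

  # degenerate 0/0 cases are zero and flagged
  cm0 <- matrix(c(0, 3, 0, 0, 5, 0, 0, 0, rep(0, 8)), 4, 4)
  prf0 <- precision_recall_f1(cm0)
  expect_equal(prf0$precision[1], 0)
  expect_equal(prf0$recall[1], 0)
  expect_equal(prf0$f1[1], 0)
  expect_true(prf0$degenerate[1])
  expect_error(precision_recall_f1(matrix(-1, 4, 4)), "non-negative")

  # accuracy identity and the F1 harmonic-mean identity on random matrices
  withr::with_seed(10, {
    for (rep in 1:5) {
      truth <- sample(1:4, 60, replace = TRUE)
      est <- sample(1:4, 60, replace = TRUE)
      cmr <- confusion_matrix(truth, est)
      expect_equal(accuracy(cmr), sum(diag(cmr)) / sum(cmr))
      prfr <- precision_recall_f1(cmr)
      ok <- prfr$precision + prfr$recall > 0
      expect_equal(prfr$f1[ok],
                   2 * prfr$precision[ok] * prfr$recall[ok] /
                     (prfr$precision[ok] + prfr$recall[ok]))
    }
  })
})

test_that("one-vs-rest AUC equals brute-force pair counting", {
  # perfectly separated scores
  scores <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(roc_auc_ovr(scores, c(1, 1, 2, 2))$auc, c(1, 1))
  # all ties
  same <- matrix(0.5, 10, 2)
  expect_equal(roc_auc_ovr(same, rep(1:2, 5))$auc, c(0.5, 0.5))
  # random case vs the all-pairs oracle
  withr::with_seed(9, {
    n <- 50
    sc <- matrix(stats::runif(n * 4), n)
    labs <- sample(1:4, n, replace = TRUE)
    got <- roc_auc_ovr(sc, labs)
    for (cls in 1:4) {
      expect_lt(abs(got$auc[cls] - oracle_auc_pairs(sc[, cls], labs == cls)),
                1e-12)
    }
  })
  # single-class labels: undefined, reported missing
  expect_true(is.na(roc_auc_ovr(matrix(stats::runif(12), 6), rep(1, 6))$auc[2]))
})

test_that("rmse, mae and psnr match their closed forms", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(mae(c(0, 0), c(1, 1)), 1)
  withr::with_seed(4, {
    a <- stats::rnorm(40); b <- stats::rnorm(40)
    s2 <- 0; s1 <- 0
    for (i in seq_along(a)) {
      s2 <- s2 + (a[i] - b[i])^2
      s1 <- s1 + abs(a[i] - b[i])
    }
    expect_lt(abs(rmse(a, b) - sqrt(s2 / 40)), 1e-12)
    expect_lt(abs(mae(a, b) - s1 / 40), 1e-12)
  })
  expect_error(rmse(1:3, 1:4), "Shapes")
  expect_error(mae(matrix(1, 2, 2), matrix(1, 2, 3)), "Shapes")

  expect_equal(psnr(rep(0.1, 100), rep(0, 100), max_value = 1), 20)
  p <- psnr(1:5, 1:5)
  expect_true(is.infinite(p) && isTRUE(attr(p, "infinite")))
  expect_equal(psnr(rep(255, 10), rep(0, 10), max_value = 255), 0)
  expect_error(psnr(1:3, 1:3, max_value = 0), "positive")
})

test_that("reference predictors satisfy their exactness contracts", {
  # persistence on a constant signal: zero error at every horizon
  t <- (0:299) / 20
  const <- resp_signal(tibble::tibble(time_s = t, si_mm = 2, ap_mm = 2,
                                      lr_mm = 2,
                                      clean_si_mm = 2, clean_ap_mm = 2,
                                      clean_lr_mm = 2), 20)
  w <- make_windows(const, label = tibble::tibble(motion_class = 1L,
                                                  excessive = FALSE))
  pred <- reference_predictor("persistence")(w)
  expect_lt(max(abs(pred - w$reg_targets)), 1e-12)

  # linear extrapolation on an exact line: zero error at every horizon
  x <- 0.01 * (0:299)
  line <- resp_signal(tibble::tibble(time_s = t, si_mm = x, ap_mm = x,
                                     lr_mm = x, clean_si_mm = x,
                                     clean_ap_mm = x, clean_lr_mm = x), 20)
  wl <- make_windows(line, label = tibble::tibble(motion_class = 1L,
                                                  excessive = FALSE))
  predl <- reference_predictor("linear_extrapolation")(wl)
  expect_lt(max(abs(predl - wl$reg_targets)), 1e-9)
  expect_error(reference_predictor("arima"))
})

test_that("evaluation reports aggregate consistently and recompute from residuals", {
  ds <- simulate_breathing(8, seed = 12)
  w <- prepare_windows(ds, window_spec(stride = 300))
  cfg <- motion_net_config(epochs = 1, seed = 2)
  fit <- fit_motion_net(w, cfg)
  rep <- latency_sweep(fit, w, keep_residuals = TRUE)

  expect_true(all(rep$per_class$precision >= 0 & rep$per_class$precision <= 1))
  expect_true(all(rep$rmse_table$rmse >= 0))
  expect_equal(sum(rep$confusion), n_windows(w))
  expect_equal(accuracy(rep$confusion), rep$summary$accuracy)

  # per-horizon RMSE recomputed from the residual dump matches the report
  hz <- w$spec$horizons_samples
  for (hi in seq_along(hz)) {
    for (a in c("si", "ap", "lr")) {
      res <- rep$residuals[[paste0("res_h", hz[hi], "_", a)]]
      want <- rep$rmse_table$rmse[rep$rmse_table$horizon_samples == hz[hi] &
                                    rep$rmse_table$axis == a]
      expect_lt(abs(sqrt(mean(res^2)) - want), 1e-12)
    }
  }
  # axis-averaged values equal the mean of the per-axis entries
  for (hi in seq_along(hz)) {
    tab <- rep$rmse_table[rep$rmse_table$horizon_samples == hz[hi], ]
    expect_equal(rep$rmse_by_latency$rmse_all_axes[hi], mean(tab$rmse))
  }
  # tidy/glance surfaces
  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(glance(rep)$n_windows, n_windows(w))
  expect_error(latency_sweep(fit, subset_windows(w, integer(0))), "Empty")
})
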