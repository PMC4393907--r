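small_engine <- function(...) {
  args <- utils::modifyList(
    list(predictor = "lnu", trainer = "lm", n = 6, n_s = 5, N_train = 20,
         sampling_hz = 10, epochs_pretrain = 50, epochs_retrain = 2, seed = 1),
    list(...))
  do.call(engine_config, args)
}

test_that("engine configuration enforces the architecture/trainer contract", {
  expect_error(engine_config(predictor = "mlp", trainer = "gd", n = 5,
                             N_train = 10, sampling_hz = 10),
               "LNU/QNU only")
  cfg <- engine_config(predictor = "qnu", trainer = "mlm", n = 5,
                       N_train = 10, sampling_hz = 15)
  expect_equal(cfg$n_s, 15)        # default horizon: one second
  expect_equal(cfg$mu, 5e-5)       # trainer-specific damping default
  expect_equal(engine_config(predictor = "lnu", trainer = "lm", n = 5,
                             N_train = 10, sampling_hz = 30)$mu, 0.01)
  expect_error(engine_config(n = 0, N_train = 10, sampling_hz = 10), "'n'")
  expect_error(engine_config(n = 5, N_train = 0, sampling_hz = 10), "N_train")
  expect_error(engine_config(n = 5, N_train = 10, sampling_hz = 10, n_s = 0.5),
               "n_s")
})

test_that("window assembly builds the documented pattern geometry", {
  # ramp series: sample value equals its 1-based index, so indices are
  # recoverable from de-normalized values
  len <- 60
  m <- matrix(rep(seq_len(len), 3), len, 3)
  n <- 4; ns <- 3; N <- 10
  end <- 50
  win <- assemble_window(m, end, n, ns, N)
  ax <- win$axes[[1]]
  expect_equal(ax$N, N)
  # targets are the N newest samples ending at end
  expect_equal(ax$y * win$sd[1] + win$mean[1], (end - N + 1):end)
  # regressor for target t holds samples t-ns, ..., t-ns-n+1 (newest first)
  for (r in c(1, 5, N)) {
    t <- end - N + r
    expect_equal(ax$X[r, ], c(1, ((t - ns):(t - ns - n + 1) - win$mean[1]) /
                                win$sd[1]))
  }
  # normalized targets have mean 0, sd 1
  expect_equal(mean(ax$y), 0, tolerance = 1e-12)
  expect_equal(stats::sd(ax$y), 1, tolerance = 1e-12)
})

test_that("N_train = 1 yields exactly one pattern targeting the end sample", {
  m <- matrix(rnorm(90), 30, 3)
  win <- assemble_window(m, 25, 4, 3, 1)
  ax <- win$axes[[2]]
  expect_equal(ax$N, 1)
  expect_equal(ax$y * win$sd[2] + win$mean[2], m[25, 2])
})

test_that("consecutive windows are pure one-sample slides", {
  set.seed(3)
  m <- matrix(rnorm(300), 100, 3)
  n <- 5; ns <- 4; N <- 12
  w1 <- assemble_window(m, 60, n, ns, N)
  w2 <- assemble_window(m, 61, n, ns, N)
  for (a in 1:3) {
    raw1 <- w1$axes[[a]]$y * w1$sd[a] + w1$mean[a]
    raw2 <- w2$axes[[a]]$y * w2$sd[a] + w2$mean[a]
    # drop the oldest pattern of w1 and the newest of w2: identical targets
    expect_equal(raw1[-1], raw2[-N])
    # regressors likewise shift by exactly one index
    X1 <- w1$axes[[a]]$X[-1, -1] * w1$sd[a] + w1$mean[a]
    X2 <- w2$axes[[a]]$X[-N, -1] * w2$sd[a] + w2$mean[a]
    expect_equal(X1, X2)
  }
})

test_that("insufficient history is reported with the first valid index", {
  m <- matrix(rnorm(60), 20, 3)
  expect_error(assemble_window(m, 10, 6, 5, 20), "first valid index 30")
  expect_error(assemble_window(m, 25, 2, 2, 5), "beyond series length")
  tr <- simulate_motion(duration_s = 1, fs = 10, seed = 1)
  expect_error(track_motion(tr, small_engine()), "insufficient history")
})

test_that("de-normalization inverts normalization under an identity surrogate", {
  set.seed(9)
  m <- matrix(rnorm(300, 10, 4), 100, 3)
  cfg <- small_engine()
  # LNU weights (0, 1, 0, ...) pass the newest normalized sample through
  ident <- lapply(1:3, function(a) lnu_weights(c(0, 1, rep(0, cfg$n - 1)), cfg$n))
  p <- predict_next(ident, m, 60, cfg)
  expect_equal(p$k, 60 + cfg$n_s)
  expect_equal(p$y_hat, m[60, ])
})

test_that("a constant trace is predicted at its level", {
  m <- matrix(8.25, 120, 3)
  fit <- track_motion(m, engine_config(predictor = "lnu", trainer = "lm",
                                       n = 4, n_s = 5, N_train = 15,
                                       sampling_hz = 10, epochs_pretrain = 100,
                                       epochs_retrain = 1, seed = 2),)
  scored <- !is.na(fit$records$e3d)
  expect_true(all(abs(fit$records$y1_hat[scored] - 8.25) < 1e-6))
  expect_equal(max(fit$records$e3d[scored]), 0, tolerance = 1e-6)
})

test_that("prediction indices, scoring and determinism obey the engine contract", {
  tr <- simulate_motion(duration_s = 25, fs = 10, seed = 6)
  cfg <- small_engine()
  fit <- track_motion(tr, cfg)
  e0 <- cfg$N_train + cfg$n_s + cfg$n - 1
  # first record predicts e0 + n_s (0-based k: e0 + n_s - 1)
  expect_equal(fit$records$k[1], e0 + cfg$n_s - 1)
  expect_equal(diff(fit$records$k), rep(1, nrow(fit$records) - 1))
  # trailing n_s predictions extend beyond the trace and are unscored
  expect_equal(sum(is.na(fit$records$e3d)), cfg$n_s)
  expect_equal(fit$n_scored, nrow(fit$records) - cfg$n_s)
  # e3d recombines the per-axis errors
  sc <- !is.na(fit$records$e3d)
  expect_equal(fit$records$e3d[sc],
               sqrt(fit$records$e1[sc]^2 + fit$records$e2[sc]^2 +
                      fit$records$e3[sc]^2))
  # same trace + config => identical record stream
  expect_identical(fit$records, track_motion(tr, cfg)$records)
})

test_that("predictions are causal: future samples never influence them", {
  tr <- simulate_motion(duration_s = 25, fs = 10, seed = 7)
  cfg <- small_engine()
  full <- track_motion(tr, cfg)
  # corrupt everything after sample 200; predictions made at ends <= 200
  # must be unchanged
  m2 <- as.matrix(tr[, 2:4])
  m2[201:nrow(m2), ] <- 1e6
  cut <- track_motion(m2, cfg)
  made_at <- full$records$k + 1 - cfg$n_s     # 1-based end index of each emit
  keep <- made_at <= 200
  expect_equal(full$records[keep, c("y1_hat", "y2_hat", "y3_hat")],
               cut$records[keep, c("y1_hat", "y2_hat", "y3_hat")])
})

test_that("epochs_retrain = 0 freezes the pretrained weights but keeps predicting", {
  tr <- simulate_motion(duration_s = 25, fs = 10, seed = 8)
  cfg <- small_engine(epochs_retrain = 0)
  fit <- track_motion(tr, cfg)
  expect_gt(nrow(fit$records), 50)
  # manual pretraining on the earliest window reproduces the final state
  e0 <- cfg$N_train + cfg$n_s + cfg$n - 1
  win <- assemble_window(tr, e0, cfg$n, cfg$n_s, cfg$N_train)
  for (a in 1:3) {
    w0 <- init_weights("lnu", cfg$n, seed = cfg$seed + a - 1)
    res <- train_predictor(w0, win$axes[[a]],
                           train_config("lm", cfg$mu, cfg$epochs_pretrain))
    expect_equal(coef(fit)[[a]]$w, res$weights$w)
  }
})

test_that("a noise-free sinusoid is predicted to numerical accuracy by the linear unit", {
  tr <- sinusoid_trace(40, fs = 15)
  fit <- track_motion(tr, engine_config(predictor = "lnu", trainer = "lm",
                                        n = 15, n_s = 15, N_train = 45,
                                        sampling_hz = 15, epochs_pretrain = 200,
                                        epochs_retrain = 2, seed = 3))
  expect_lt(mae_3d(fit, last_s = 20)$mae_mm, 1e-6)
})

test_that("the quadratic unit under MLM matches the linear unit on a sinusoid", {
  tr <- sinusoid_trace(40, fs = 15)
  args <- list(n = 15, n_s = 15, N_train = 45, sampling_hz = 15, seed = 3)
  ml <- mae_3d(do.call(track_motion, c(list(tr, predictor = "lnu",
                                            trainer = "mlm"), args)),
               last_s = 20)$mae_mm
  mq <- mae_3d(do.call(track_motion, c(list(tr, predictor = "qnu",
                                            trainer = "mlm"), args)),
               last_s = 20)$mae_mm
  # both reach the numerical noise floor; the QNU (which nests the LNU) is
  # no worse than twice the linear baseline up to that floor
  expect_lt(mq, max(2 * ml, 1e-9))
})

test_that("gradient-descent adaptation tracks the signal sample by sample", {
  tr <- sinusoid_trace(40, fs = 10)
  fit <- track_motion(tr, engine_config(predictor = "qnu", trainer = "gd",
                                        n = 8, n_s = 10, N_train = 30,
                                        sampling_hz = 10, mu = 0.9,
                                        epochs_pretrain = 100, seed = 4))
  # normalized GD is crude but must stay bounded and broadly follow the 10 mm
  # signal
  expect_true(all(is.finite(fit$records$y1_hat)))
  expect_lt(mae_3d(fit, last_s = 15)$mae_mm, 10)
})

test_that("prediction records round-trip through the CSV interface", {
  tr <- simulate_motion(duration_s = 25, fs = 10, seed = 10)
  fit <- track_motion(tr, small_engine())
  f <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(fit, f)
  back <- read_records_csv(f)
  expect_equal(back$e3d, fit$records$e3d, tolerance = 1e-12)
  expect_equal(back$k, fit$records$k)
  writeLines("a,b\n1,2", f)
  expect_error(read_records_csv(f), "records format error")
})

test_that("fit accessors expose predictions, residuals and states", {
  tr <- simulate_motion(duration_s = 25, fs = 10, seed = 11)
  fit <- track_motion(tr, small_engine())
  expect_length(coef(fit), 3)
  expect_s3_class(coef(fit)[[1]], "lnu_weights")
  expect_equal(dim(residuals(fit)), c(fit$n_scored, 3))
  expect_equal(nrow(fitted(fit)), nrow(fit$records))
  p <- predict(fit, tr)
  expect_equal(p$k, nrow(tr) + fit$config$n_s)
  expect_length(p$y_hat, 3)
  s <- summary(fit)
  expect_s3_class(s, "motion_eval")
  expect_output(print(s), "3D MAE")
})
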