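test_that("sum of squared errors matches the elementwise oracle", {
  d <- make_qnu_data(n = 3, N = 20, seed = 7)
  w <- qnu_weights(d$w_true, 3)
  expect_equal(sse(w, d$ts), 0)
  # zero weights, unit targets
  ts1 <- training_set(cbind(1, matrix(0, 5, 2)), rep(1, 5))
  expect_equal(sse(qnu_weights(rep(0, 6), 2), ts1), 5)
  # random case vs naive loop
  set.seed(8)
  wr <- qnu_weights(stats::rnorm(qnu_weight_count(3)), 3)
  acc <- 0
  for (k in seq_len(d$ts$N))
    acc <- acc + (d$ts$y[k] - oracle_qnu_forward(wr$w, d$ts$X[k, ]))^2
  expect_equal(sse(wr, d$ts), acc)
})

test_that("QNU Jacobian is the constant quadratic design matrix", {
  x <- c(1, 0.5, -2)
  ts <- training_set(matrix(x, 1, 3, byrow = TRUE), 0)
  expect_equal(as.vector(jacobian_qnu(ts)),
               c(1, 0.5, -2, 0.25, -1, 4))
  # finite-difference agreement
  d <- make_qnu_data(n = 4, N = 8, seed = 3)
  w <- init_weights("qnu", 4, seed = 1)
  expect_equal(jacobian_qnu(d$ts), oracle_fd_jacobian(w, d$ts$X),
               tolerance = 1e-6)
  # shape for the large architecture
  ts30 <- training_set(matrix(c(1, stats::rnorm(30)), 1, 31, byrow = TRUE), 0)
  expect_equal(dim(jacobian_qnu(ts30)), c(1, 496))
})

test_that("MLP Jacobian blocks match analytic special cases and finite differences", {
  n <- 3; n1 <- 2; N <- 6
  set.seed(4)
  X <- cbind(1, matrix(stats::rnorm(N * n), N, n))
  ts <- training_set(X, stats::rnorm(N))
  # W = 0: phi'(0) = 1/2, hidden entry (k, j) = w_out[i] * x_kj / 2
  w <- mlp_weights(matrix(0, n1, n + 1), c(2, -3), n, n1)
  jb <- jacobian_mlp(w, ts)
  expect_equal(jb$hidden[[1]], 2 * X / 2)
  expect_equal(jb$hidden[[2]], -3 * X / 2)
  expect_equal(jb$output, matrix(0, N, n1))
  # w_out[i] = 0 zeroes that neuron's block
  w2 <- mlp_weights(matrix(stats::rnorm(n1 * (n + 1)), n1, n + 1), c(0, 1), n, n1)
  expect_equal(jacobian_mlp(w2, ts)$hidden[[1]], matrix(0, N, n + 1))
  # random small nets vs central differences
  for (seed in 1:5) {
    inst <- make_mlp_instance(n = 4, n1 = 3, N = 10, seed = seed)
    Jfd <- oracle_fd_jacobian(inst$weights, inst$ts$X)
    jb <- jacobian_mlp(inst$weights, inst$ts)
    Jan <- cbind(do.call(cbind, jb$hidden), jb$output)
    expect_lt(max(abs(Jan - Jfd)) / max(abs(Jfd)), 1e-5)
  }
})

test_that("batch L-M converges to the least-squares optimum of the QNU", {
  d <- make_qnu_data(n = 5, N = 100, seed = 42)
  w0 <- init_weights("qnu", 5, seed = 3)
  # zero error leaves the weights unchanged
  wstar <- qnu_weights(d$w_true, 5)
  expect_equal(lm_epoch(wstar, d$ts, mu = 10)$w, d$w_true)
  # exactly representable data: SSE collapses within 50 epochs
  res <- train_predictor(w0, d$ts, train_config("lm", mu = 100, epochs = 50))
  expect_lt(res$q_per_epoch[50], 1e-10 * d$ts$N)
  expect_true(res$converged)
  # one large-mu epoch lands on the normal-equations (pseudo-inverse) solve
  J <- jacobian_qnu(d$ts)
  wls <- as.vector(solve(crossprod(J), crossprod(J, d$ts$y)))
  one <- lm_epoch(init_weights("qnu", 5, seed = 9), d$ts, mu = 1e10)
  expect_equal(one$w, wls, tolerance = 1e-6)
})

test_that("inverse-free MLM reproduces the per-weight update formula", {
  # single weight, Jacobian column of ones, 1/mu = 1: dw = sum(e) / (N + 1)
  N <- 7
  set.seed(5)
  y <- stats::rnorm(N)
  ts <- training_set(matrix(1, N, 1), y)
  w0 <- lnu_weights(0, 0)
  upd <- mlm_epoch(w0, ts, mu = 1)
  expect_equal(upd$w, sum(y) / (N + 1))
  # zero error vector leaves every weight unchanged
  wfit <- lnu_weights(mean(y), 0)
  ts0 <- training_set(matrix(1, N, 1), rep(mean(y), N))
  expect_equal(mlm_epoch(wfit, ts0, mu = 1)$w, wfit$w)
  # an all-zero Jacobian column yields a finite zero update
  X <- cbind(1, rep(0, N))
  tsz <- training_set(X, y)
  updz <- mlm_epoch(lnu_weights(c(0, 0), 1), tsz, mu = 2)
  expect_equal(updz$w[2], 0)
  expect_true(all(is.finite(updz$w)))
})

test_that("MLM and LM coincide for a single-weight model to machine precision", {
  set.seed(6)
  for (rep in 1:5) {
    N <- 9
    j <- stats::rnorm(N)                       # bias-only LNU, random inputs
    y <- stats::rnorm(N)
    ts <- training_set(matrix(j, N, 1), y)
    w0 <- lnu_weights(stats::rnorm(1), 0)
    mu <- stats::runif(1, 0.01, 10)
    expect_equal(lm_epoch(w0, ts, mu)$w, mlm_epoch(w0, ts, mu)$w,
                 tolerance = 1e-14)
  }
})

test_that("MLM lowers the SSE monotonically on noise-free QNU data at small mu", {
  d <- make_qnu_data(n = 3, N = 60, seed = 10)
  res <- train_predictor(init_weights("qnu", 3, seed = 2), d$ts,
                         train_config("mlm", mu = 1e-3, epochs = 40))
  expect_true(all(diff(res$q_per_epoch) <= 1e-12))
  expect_true(res$converged)
})

test_that("normalized gradient descent follows the norm-scaled update and is stable", {
  w <- qnu_weights(rep(0.3, 6), 2)
  x <- c(1, 0, 0)                              # colx = (1, 0, ..., 0)
  mu0 <- 0.8
  target <- qnu_forward(w, x)                  # e = 0 -> no change
  expect_equal(gd_step(w, x, target, mu0)$w, w$w)
  e <- 1.7
  upd <- gd_step(w, x, w$w[1] + e, mu0)
  expect_equal(upd$w[1] - w$w[1], mu0 * e / 2) # mu(k) = mu0 / (1 + 1)
  expect_equal(upd$w[-1], w$w[-1])
  # squared-denominator reading shrinks the step
  x2 <- c(1, 2, -1)
  d1 <- gd_step(w, x2, 5, 0.5)$w - w$w
  d2 <- gd_step(w, x2, 5, 0.5, squared_denominator = TRUE)$w - w$w
  nc <- 1 + sum(colx(x2)^2)
  expect_equal(d2 * nc, d1)
  # repeated adaptation on one fixed pair contracts the error for mu0 <= 1
  set.seed(13)
  for (rep in 1:5) {
    n <- sample(1:5, 1)
    x <- c(1, stats::rnorm(n, 0, 3))
    target <- stats::rnorm(1, 0, 5)
    w <- init_weights("qnu", n, seed = rep)
    err <- abs(target - qnu_forward(w, x))
    for (it in 1:200) w <- gd_step(w, x, target, mu0 = 1)
    expect_lt(abs(target - qnu_forward(w, x)), 1e-6 * max(1, err))
  }
  expect_error(gd_step(init_weights("mlp", 3, n1 = 2, seed = 1), c(1, 1, 1, 1),
                       0, 0.5), "LNU/QNU only")
})

test_that("train_predictor composes epochs deterministically", {
  d <- make_qnu_data(n = 4, N = 50, seed = 21)
  w0 <- init_weights("qnu", 4, seed = 8)
  one <- train_predictor(w0, d$ts, train_config("lm", mu = 5, epochs = 1))
  expect_equal(one$weights$w, lm_epoch(w0, d$ts, mu = 5)$w)
  expect_length(one$q_per_epoch, 1)
  # identical data + config + seed => identical trajectories
  r1 <- train_predictor(init_weights("qnu", 4, seed = 8), d$ts,
                        train_config("mlm", mu = 1e-3, epochs = 15))
  r2 <- train_predictor(init_weights("qnu", 4, seed = 8), d$ts,
                        train_config("mlm", mu = 1e-3, epochs = 15))
  expect_identical(r1, r2)
  # q trajectory is non-increasing for LM at small fixed mu
  rl <- train_predictor(init_weights("qnu", 4, seed = 8), d$ts,
                        train_config("lm", mu = 0.5, epochs = 20))
  expect_true(all(diff(rl$q_per_epoch) <= 1e-10))
  expect_error(train_predictor(init_weights("mlp", 4, n1 = 2, seed = 1), d$ts,
                               train_config("gd", mu = 0.5, epochs = 2)),
               "LNU/QNU only")
  expect_error(train_config("lm", mu = -1, epochs = 5), "'mu'")
  expect_error(train_config("lm", mu = 1, epochs = 0), "'epochs'")
})

test_that("the adaptive damping schedule still reduces training error", {
  d <- make_qnu_data(n = 3, N = 40, seed = 30)
  res <- train_predictor(init_weights("qnu", 3, seed = 4), d$ts,
                         train_config("lm", mu = 0.01, epochs = 30,
                                      mu_schedule = TRUE))
  expect_lt(res$q_per_epoch[30], res$q_per_epoch[1])
})

test_that("MLP batch L-M reduces the SSE on a learnable target", {
  set.seed(31)
  n <- 3; N <- 40
  X <- cbind(1, matrix(stats::rnorm(N * n), N, n))
  teacher <- mlp_weights(matrix(stats::rnorm(2 * (n + 1), 0, 0.8), 2, n + 1),
                         c(1.2, -0.7), n, 2)
  y <- respredict:::forward_rows(teacher, X)
  ts <- training_set(X, y)
  w0 <- init_weights("mlp", n, n1 = 2, seed = 9)
  res <- train_predictor(w0, ts, train_config("lm", mu = 1, epochs = 100))
  expect_lt(res$q_per_epoch[100], 0.05 * sse(w0, ts))
})
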