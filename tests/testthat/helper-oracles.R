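# Independent oracles used across the suite: naive enumerations and
# finite-difference derivatives kept deliberately separate from the
# package's vectorized implementations.

# QNU output as the explicit double sum over i <= j (0-based pair indices).
oracle_qnu_forward <- function(w, x) {
  n <- length(x) - 1L
  out <- 0; idx <- 1L
  for (i in 0:n) for (j in i:n) {
    out <- out + w[idx] * x[i + 1L] * x[j + 1L]
    idx <- idx + 1L
  }
  out
}

# Quadratic expansion by plain enumeration.
oracle_colx <- function(x) {
  n <- length(x) - 1L
  out <- numeric(0)
  for (i in 0:n) for (j in i:n) out <- c(out, x[i + 1L] * x[j + 1L])
  out
}

# Central finite differences of a predictor's batch output w.r.t. the flat
# weight vector: N x P matrix.
oracle_fd_jacobian <- function(weights, X, eps = 1e-6) {
  w0 <- respredict:::flatten_weights(weights)
  P <- length(w0); N <- nrow(X)
  J <- matrix(0, N, P)
  for (p in seq_len(P)) {
    wp <- w0; wp[p] <- w0[p] + eps
    wm <- w0; wm[p] <- w0[p] - eps
    fp <- respredict:::forward_rows(respredict:::unflatten_weights(weights, wp), X)
    fm <- respredict:::forward_rows(respredict:::unflatten_weights(weights, wm), X)
    J[, p] <- (fp - fm) / (2 * eps)
  }
  J
}

# Training data generated by a known QNU: exactly representable, so batch
# least squares has the generating weights as its unique solution.
make_qnu_data <- function(n = 5, N = 100, seed = 42) {
  set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(N * n), N, n))
  w_true <- stats::runif(qnu_weight_count(n), -1, 1)
  y <- apply(X, 1, function(x) oracle_qnu_forward(w_true, x))
  list(ts = training_set(X, y), w_true = w_true)
}

# Small random MLP instance with its training set.
make_mlp_instance <- function(n = 4, n1 = 3, N = 12, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(stats::rnorm(N * n), N, n))
  w <- mlp_weights(matrix(stats::rnorm(n1 * (n + 1), 0, 0.5), n1, n + 1),
                   stats::rnorm(n1, 0, 0.5), n, n1)
  list(weights = w, ts = training_set(X, stats::rnorm(N)))
}

# A drift-free, noise-free sinusoidal trace (exactly linearly predictable).
sinusoid_trace <- function(duration_s, fs, amplitude = 10, seed = 2) {
  simulate_motion(duration_s = duration_s, fs = fs, base_period_s = 3,
                  period_drift = 0, amplitude_mm = rep(amplitude, 3),
                  amplitude_drift = 0, baseline_drift_mm_per_s = 0,
                  noise_std_mm = 0, waveform_power = 2, seed = seed)
}

# Dominant spectral period of one axis, s.
dominant_period <- function(y, fs, fmin = 0.05) {
  y <- y - mean(y)
  p <- Mod(stats::fft(y))^2
  f <- (seq_along(y) - 1) * fs / length(y)
  sel <- f > fmin & f <= fs / 2
  1 / f[sel][which.max(p[sel])]
}

population_sd <- function(x) sqrt(mean((x - mean(x))^2))
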