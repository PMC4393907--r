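#' Training set of input-target patterns
#'
#' Couples a matrix of regressor rows with the scalar targets `n_s` samples
#' ahead, both in normalized units.
#'
#' @param X numeric matrix, one regressor per row (leading bias column of
#'   ones).
#' @param y numeric target vector, one per row of `X`.
#' @return a `training_set` list with elements `X`, `y`, `N`, `n`.
#' @export
training_set <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("training set needs at least one pattern", call. = FALSE)
  if (nrow(X) != length(y))
    stop(sprintf("training set has %d regressors but %d targets", nrow(X),
                 length(y)), call. = FALSE)
  structure(list(X = X, y = as.numeric(y), N = nrow(X), n = ncol(X) - 1L),
            class = "training_set")
}

check_ts <- function(weights, ts) {
  if (ts$n != weights$n)
    stop(sprintf("architecture error: training set has n=%d, weights have n=%d",
                 ts$n, weights$n), call. = FALSE)
}

#' Sum of squared prediction errors
#'
#' \eqn{Q = \sum_k (y_k - \hat y_k)^2} over a training set, the epoch-wise
#' training criterion.
#'
#' @param weights a weight object.
#' @param ts a [training_set()].
#' @return non-negative scalar.
#' @export
sse <- function(weights, ts) {
  check_ts(weights, ts)
  e <- ts$y - forward_rows(weights, ts$X)
  sum(e * e)
}

#' Jacobian of the QNU (and LNU) forward map
#'
#' For in-parameter-linear units the Jacobian of the outputs with respect
#' to the weights is just the design matrix — row `k` is `colx` of the
#' `k`-th regressor (QNU) or the regressor itself (LNU) — independent of
#' the weights, so it is computed once per retraining window.
#'
#' @param ts a [training_set()].
#' @return `N x m` numeric matrix.
#' @export
jacobian_qnu <- function(ts) colx_matrix(ts$X)

#' @rdname jacobian_qnu
#' @export
jacobian_lnu <- function(ts) ts$X

#' Jacobian blocks of the MLP forward map
#'
#' For hidden neuron `i` the block is the `N x (n+1)` matrix with entries
#' \eqn{w_{out,i}\,\phi'(W_i x_k)\,x_{k,j}}; the output-weight block has
#' entries \eqn{\phi(W_i x_k)}. \eqn{\phi'(v) = (1-\phi(v)^2)/2}.
#'
#' @param weights an [mlp_weights()] object.
#' @param ts a [training_set()].
#' @return list with `hidden` (list of `n1` matrices) and `output`
#'   (`N x n1` matrix).
#' @export
jacobian_mlp <- function(weights, ts) {
  check_ts(weights, ts)
  V <- ts$X %*% t(weights$W)            # N x n1 pre-activations
  Phi <- unit_sigmoid(V)
  Phip <- unit_sigmoid_deriv(Phi)
  hidden <- lapply(seq_len(weights$n1), function(i)
    (weights$w_out[i] * Phip[, i]) * ts$X)
  list(hidden = hidden, output = Phi)
}

# Full flat Jacobian (N x P) in flatten_weights() order; shared by MLM and
# the finite-difference checks.
jacobian_flat <- function(weights, ts) {
  switch(weights$kind,
    lnu = jacobian_lnu(ts),
    qnu = jacobian_qnu(ts),
    mlp = {
      jb <- jacobian_mlp(weights, ts)
      cbind(do.call(cbind, jb$hidden), jb$output)
    })
}

chol_damped <- function(A, mu) {
  tryCatch(chol(A + diag(1 / mu, nrow(A))),
           error = function(e)
             stop("numerical error: damped normal equations are singular; ",
                  "reduce mu (stronger damping)", call. = FALSE))
}

# Precompute the per-window constants of a batch L-M run. For LNU/QNU the
# Jacobian is weight-independent, so the Cholesky factor of (J'J + I/mu) is
# formed once and every epoch costs two matrix-vector products.
lm_prepare <- function(weights, ts, mu) {
  if (weights$kind == "mlp") return(NULL)
  J <- jacobian_flat(weights, ts)
  list(J = J, R = chol_damped(crossprod(J), mu))
}

#' One epoch of batch Levenberg-Marquardt
#'
#' Damped Gauss-Newton: per weight block `i`,
#' \eqn{\Delta w_i = (J_i^T J_i + I/\mu)^{-1} J_i^T e}, all blocks stepping
#' from the same error vector `e` evaluated at the entry weights. LNU and
#' QNU form a single block (their Jacobian is the constant design matrix);
#' the MLP uses one block per hidden neuron plus one for the output
#' weights.
#'
#' @param weights a weight object.
#' @param ts a [training_set()].
#' @param mu learning rate; `1/mu` is the ridge damping added to the
#'   normal equations.
#' @param prep optional precomputation from an earlier epoch on the same
#'   window (LNU/QNU only).
#' @return updated weights.
#' @export
lm_epoch <- function(weights, ts, mu, prep = NULL) {
  check_ts(weights, ts)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (weights$kind %in% c("lnu", "qnu")) {
    if (is.null(prep)) prep <- lm_prepare(weights, ts, mu)
    e <- ts$y - as.vector(prep$J %*% weights$w)
    dw <- backsolve(prep$R, forwardsolve(t(prep$R), crossprod(prep$J, e)))
    weights$w <- weights$w + as.vector(dw)
    return(weights)
  }
  # MLP: error fixed at entry, one damped step per block
  e <- ts$y - forward_rows(weights, ts$X)
  jb <- jacobian_mlp(weights, ts)
  Wnew <- weights$W
  for (i in seq_len(weights$n1)) {
    Ji <- jb$hidden[[i]]
    R <- chol_damped(crossprod(Ji), mu)
    Wnew[i, ] <- Wnew[i, ] +
      as.vector(backsolve(R, forwardsolve(t(R), crossprod(Ji, e))))
  }
  Ro <- chol_damped(crossprod(jb$output), mu)
  weights$w_out <- weights$w_out +
    as.vector(backsolve(Ro, forwardsolve(t(Ro), crossprod(jb$output, e))))
  weights$W <- Wnew
  weights
}

#' Precompute the inverse-free L-M update vectors
#'
#' For every scalar weight with Jacobian column `j`, the modified
#' Levenberg-Marquardt update is \eqn{\Delta w = \tilde j \cdot e} with
#' \eqn{\tilde j = j^T / (j^T j + 1/\mu)} — a scalar division instead of a
#' matrix inverse. All \eqn{\tilde j} are assembled once per retraining
#' window; epochs then only refresh the error vector. For LNU/QNU the
#' Jacobian itself is window-constant, so the whole retraining loop is
#' inversion-free.
#'
#' @inheritParams lm_epoch
#' @return list with `Jt` (`P x N` matrix of \eqn{\tilde j} rows) ready for
#'   [mlm_epoch()].
#' @export
mlm_precompute <- function(weights, ts, mu) {
  check_ts(weights, ts)
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  J <- jacobian_flat(weights, ts)
  d <- colSums(J * J) + 1 / mu     # all-zero columns stay harmless: d >= 1/mu
  list(Jt = t(J) / d)
}

#' One epoch of modified (inverse-free) Levenberg-Marquardt
#'
#' Applies \eqn{\Delta w = \tilde j \cdot e} simultaneously to every scalar
#' weight, with one shared error vector recomputed per epoch.
#'
#' @inheritParams lm_epoch
#' @param prep precomputation from [mlm_precompute()]; computed on the fly
#'   (at the current weights) when omitted.
#' @return updated weights.
#' @export
mlm_epoch <- function(weights, ts, mu, prep = NULL) {
  check_ts(weights, ts)
  if (is.null(prep)) prep <- mlm_precompute(weights, ts, mu)
  e <- ts$y - forward_rows(weights, ts$X)
  unflatten_weights(weights, flatten_weights(weights) +
                      as.vector(prep$Jt %*% e))
}

#' One sample-wise normalized gradient-descent update
#'
#' Normalized-LMS adaptation for the in-parameter-linear units:
#' \eqn{\Delta w = \mu(k)\, e(k)\, \mathrm{colx}(k)} with
#' \eqn{\mu(k) = \mu_0 / (1 + \lVert \mathrm{colx}(k) \rVert^2)} (LNU uses
#' the plain regressor in place of `colx`). The norm-scaled rate keeps the
#' update stable for any bounded input when \eqn{\mu_0 \le 1}.
#'
#' @param weights an LNU or QNU weight object.
#' @param x regressor vector.
#' @param target desired output (normalized units).
#' @param mu0 base learning rate (> 0).
#' @param squared_denominator use \eqn{\mu_0/(1+\lVert colx\rVert^2)^2}
#'   instead of the standard normalized-LMS denominator.
#' @return updated weights.
#' @export
gd_step <- function(weights, x, target, mu0, squared_denominator = FALSE) {
  if (!is.numeric(mu0) || mu0 <= 0) stop("mu0 must be > 0", call. = FALSE)
  if (weights$kind == "mlp")
    stop("gradient-descent adaptation is defined for LNU/QNU only", call. = FALSE)
  check_regressor(weights, x)
  cx <- if (weights$kind == "qnu") colx(x) else x
  e <- target - sum(weights$w * cx)
  den <- 1 + sum(cx * cx)
  if (squared_denominator) den <- den * den
  weights$w <- weights$w + (mu0 / den) * e * cx
  weights
}

# One in-order pass of gd_step over every pattern of a window.
gd_pass <- function(weights, ts, mu0, squared_denominator = FALSE) {
  for (k in seq_len(ts$N))
    weights <- gd_step(weights, ts$X[k, ], ts$y[k], mu0, squared_denominator)
  weights
}

#' Training configuration
#'
#' @param algorithm `"lm"` (batch Levenberg-Marquardt), `"mlm"`
#'   (inverse-free modified L-M) or `"gd"` (sample-wise normalized
#'   gradient descent).
#' @param mu learning rate: ridge damping `1/mu` for LM/MLM, base rate
#'   `mu0` for GD.
#' @param epochs iteration count (LM/MLM: damped steps; GD: in-order
#'   passes over the window).
#' @param mu_schedule for LM only: classical adaptive damping (`mu` grows
#'   tenfold after an epoch that lowers the SSE — weaker damping — and
#'   shrinks tenfold after one that raises it). Off by default — a fixed
#'   `mu` matches how the predictors are run online.
#' @param gd_squared_denominator see [gd_step()].
#' @return a `train_config` list.
#' @export
train_config <- function(algorithm = c("lm", "mlm", "gd"), mu, epochs,
                         mu_schedule = FALSE, gd_squared_denominator = FALSE) {
  algorithm <- match.arg(algorithm)
  if (!is.numeric(mu) || length(mu) != 1 || mu <= 0)
    stop("configuration error: field 'mu' must be > 0", call. = FALSE)
  if (!is.numeric(epochs) || length(epochs) != 1 || epochs < 1 ||
      epochs != round(epochs))
    stop("configuration error: field 'epochs' must be a positive integer",
         call. = FALSE)
  structure(list(algorithm = algorithm, mu = as.numeric(mu),
                 epochs = as.integer(epochs), mu_schedule = isTRUE(mu_schedule),
                 gd_squared_denominator = isTRUE(gd_squared_denominator)),
            class = "train_config")
}

#' Train a predictor on a window of patterns
#'
#' Runs the selected algorithm for a fixed number of epochs (no early
#' stopping), recording the sum-of-squared-errors trajectory.
#'
#' @param weights initial weights.
#' @param ts a [training_set()].
#' @param config a [train_config()].
#' @return a `training_result`: list with `weights`, `q_per_epoch` (SSE
#'   after each epoch) and `converged` (all epochs finite and the final
#'   SSE no worse than the initial one).
#' @export
train_predictor <- function(weights, ts, config) {
  check_ts(weights, ts)
  if (!inherits(config, "train_config")) config <- do.call(train_config, config)
  if (config$algorithm == "gd" && weights$kind == "mlp")
    stop("gradient-descent adaptation is defined for LNU/QNU only", call. = FALSE)
  q0 <- sse(weights, ts)
  q <- numeric(config$epochs)
  mu <- config$mu
  prep <- switch(config$algorithm,
                 lm = if (!config$mu_schedule) lm_prepare(weights, ts, mu),
                 mlm = mlm_precompute(weights, ts, mu),
                 NULL)
  q_prev <- q0
  for (ep in seq_len(config$epochs)) {
    weights <- switch(config$algorithm,
      lm = lm_epoch(weights, ts, mu, prep),
      mlm = mlm_epoch(weights, ts, mu, prep),
      gd = gd_pass(weights, ts, mu, config$gd_squared_denominator))
    q[ep] <- sse(weights, ts)
    if (config$algorithm == "lm" && config$mu_schedule) {
      mu <- if (q[ep] <= q_prev) mu * 10 else mu / 10
      q_prev <- q[ep]
    }
  }
  structure(list(weights = weights, q_per_epoch = q,
                 converged = all(is.finite(q)) && q[config$epochs] <= q0),
            class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  cat(sprintf("training result: %d epochs, SSE %.4g -> %.4g (%s)\n",
              length(x$q_per_epoch), x$q_per_epoch[1],
              x$q_per_epoch[length(x$q_per_epoch)],
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
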