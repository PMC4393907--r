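#' Configuration of the online prediction engine
#'
#' Bundles the architecture, trainer and sliding-window geometry for
#' [track_motion()]. The engine predicts `n_s` samples ahead (at
#' `sampling_hz` Hz, `n_s = sampling_hz` is a 1 s horizon), retraining at
#' every new sample on the most recent `N_train` input-target patterns,
#' each window z-normalized per axis.
#'
#' Defaults follow the operating points found best for this predictor
#' family: damping rate `mu` of 5e-5 for MLM, 0.01 for batch L-M, base
#' rate 0.5 for normalized GD; 800 pretraining epochs (400 for GD) and 8
#' retraining epochs per sample.
#'
#' @param predictor `"lnu"`, `"qnu"` or `"mlp"`.
#' @param trainer `"lm"`, `"mlm"` or `"gd"` (GD applies to LNU/QNU only).
#' @param n lagged inputs per regressor.
#' @param n_s prediction horizon in samples (default: one second, i.e.
#'   `sampling_hz`).
#' @param N_train patterns per retraining window.
#' @param sampling_hz sampling frequency the engine expects, Hz.
#' @param n1 hidden neurons (MLP only).
#' @param mu learning rate (see [train_config()]); trainer-specific
#'   default when `NULL`.
#' @param epochs_pretrain epochs for the initial batch pretraining.
#' @param epochs_retrain epochs per sliding-window retraining; 0 freezes
#'   the weights after pretraining.
#' @param gd_passes GD retraining granularity: 0 (default) performs one
#'   normalized-GD update on the newest pattern per sample; a positive
#'   value runs that many full passes over the window instead.
#' @param seed base seed for the per-axis initial weights.
#' @param warm_start retrain from the previous sample's weights (default)
#'   or re-initialize at every window (ablation).
#' @param mu_schedule,gd_squared_denominator passed to [train_config()] /
#'   [gd_step()].
#' @return an `engine_config`.
#' @export
engine_config <- function(predictor = c("qnu", "lnu", "mlp"),
                          trainer = c("mlm", "lm", "gd"),
                          n = 30, n_s = NULL, N_train = 90,
                          sampling_hz = 15, n1 = NULL, mu = NULL,
                          epochs_pretrain = NULL, epochs_retrain = NULL,
                          gd_passes = 0, seed = 1L, warm_start = TRUE,
                          mu_schedule = FALSE, gd_squared_denominator = FALSE) {
  predictor <- match.arg(predictor)
  trainer <- match.arg(trainer)
  if (predictor == "mlp" && trainer == "gd")
    stop("configuration error: gradient-descent adaptation is defined for ",
         "LNU/QNU only, not MLP", call. = FALSE)
  if (!is.numeric(sampling_hz) || sampling_hz <= 0)
    stop("configuration error: field 'sampling_hz' must be > 0", call. = FALSE)
  if (is.null(n_s)) n_s <- round(sampling_hz)
  if (!is.numeric(n_s) || n_s < 1 || n_s != round(n_s))
    stop("configuration error: field 'n_s' must be a positive integer", call. = FALSE)
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop("configuration error: field 'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(N_train) || N_train < 1 || N_train != round(N_train))
    stop("configuration error: field 'N_train' must be a positive integer",
         call. = FALSE)
  if (predictor == "mlp") {
    if (is.null(n1)) n1 <- 3L
    if (!is.numeric(n1) || n1 < 1 || n1 != round(n1))
      stop("configuration error: field 'n1' must be a positive integer", call. = FALSE)
  }
  if (is.null(mu)) mu <- switch(trainer, mlm = 5e-5, lm = 0.01, gd = 0.5)
  if (is.null(epochs_pretrain))
    epochs_pretrain <- if (trainer == "gd") 400L else 800L
  if (is.null(epochs_retrain)) epochs_retrain <- if (trainer == "gd") 1L else 8L
  if (!is.numeric(epochs_retrain) || epochs_retrain < 0)
    stop("configuration error: field 'epochs_retrain' must be >= 0", call. = FALSE)
  structure(list(predictor = predictor, trainer = trainer,
                 n = as.integer(n), n_s = as.integer(n_s),
                 N_train = as.integer(N_train),
                 sampling_hz = as.numeric(sampling_hz),
                 n1 = if (predictor == "mlp") as.integer(n1) else NULL,
                 mu = as.numeric(mu),
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_retrain = as.integer(epochs_retrain),
                 gd_passes = as.integer(gd_passes),
                 seed = as.integer(seed), warm_start = isTRUE(warm_start),
                 mu_schedule = isTRUE(mu_schedule),
                 gd_squared_denominator = isTRUE(gd_squared_denominator)),
            class = "engine_config")
}

#' @export
print.engine_config <- function(x, ...) {
  cat(sprintf("engine: %s + %s | n=%d n_s=%d N_train=%d @ %g Hz%s | mu=%g, epochs %d/%d\n",
              toupper(x$predictor), toupper(x$trainer), x$n, x$n_s, x$N_train,
              x$sampling_hz,
              if (!is.null(x$n1)) sprintf(" n1=%d", x$n1) else "",
              x$mu, x$epochs_pretrain, x$epochs_retrain))
  invisible(x)
}

# First 1-based sample index that can terminate a full window.
first_valid_end <- function(n, n_s, N_train) N_train + n_s + n - 1L

# z-normalization statistics of a window: mean and sd (clamped) of the
# N_train raw samples of the retraining window proper.
window_stats <- function(col, end, N_train) {
  seg <- col[(end - N_train + 1L):end]
  m <- mean(seg)
  s <- stats::sd(seg)
  if (!is.finite(s) || s < 1e-12) s <- 1
  c(m, s)
}

#' Assemble a normalized sliding retraining window
#'
#' Builds the `N_train` newest input-target patterns ending at
#' `end_index`: the pattern with target index `t` pairs the target
#' `y(t)` with the regressor over samples `t - n_s, ..., t - n_s - n + 1`.
#' Each axis is z-normalized with the mean and standard deviation of the
#' raw retraining window (the `N_train` target samples), applied to
#' regressor samples and targets alike; the statistics are retained so
#' predictions can be mapped back to millimetres. A window whose standard
#' deviation vanishes (constant samples) is centred only.
#'
#' @param series a `motion_trace`, or numeric matrix with one column per
#'   axis.
#' @param end_index 1-based index of the newest measured sample.
#' @param n,n_s,N_train window geometry (see [engine_config()]).
#' @return a `window_snapshot`: per-axis [training_set()]s plus `mean`,
#'   `sd` and `end_index`.
#' @export
assemble_window <- function(series, end_index, n, n_s, N_train) {
  m <- trace_matrix(series)
  need <- first_valid_end(n, n_s, N_train)
  if (end_index < need)
    stop(sprintf("insufficient history: end index %d precedes the first valid index %d",
                 end_index, need), call. = FALSE)
  if (end_index > nrow(m))
    stop(sprintf("insufficient history: end index %d beyond series length %d",
                 end_index, nrow(m)), call. = FALSE)
  lo <- end_index - (N_train + n_s + n) + 2L
  naxis <- ncol(m)
  axes <- vector("list", naxis)
  mu <- sd <- numeric(naxis)
  for (a in seq_len(naxis)) {
    st <- window_stats(m[, a], end_index, N_train)
    mu[a] <- st[1]; sd[a] <- st[2]
    z <- (m[lo:end_index, a] - st[1]) / st[2]
    X <- cbind(1, embed(z, n)[seq_len(N_train), , drop = FALSE])
    y <- z[(n + n_s):(N_train + n + n_s - 1L)]
    axes[[a]] <- training_set(X, y)
  }
  structure(list(axes = axes, mean = mu, sd = sd,
                 end_index = as.integer(end_index),
                 n = as.integer(n), n_s = as.integer(n_s),
                 N_train = as.integer(N_train)),
            class = "window_snapshot")
}

# Normalized regressor for the newest samples of one axis, ending at end.
current_regressor <- function(col, end, n, mu, sd) {
  if (end < n) insufficient_history(n, end)
  c(1, (col[end:(end - n + 1L)] - mu) / sd)
}

#' Predict `n_s` samples ahead from the newest measurements
#'
#' Builds the regressor from the samples ending at `end_index`, normalizes
#' it with the current window statistics, applies the forward map of each
#' axis' predictor and de-normalizes back to millimetres.
#'
#' @param state list of three per-axis weight objects.
#' @param series a `motion_trace` or 3-column matrix.
#' @param end_index 1-based index of the newest measured sample.
#' @param config an [engine_config()].
#' @param window optional [assemble_window()] snapshot providing the
#'   normalization statistics (assembled at `end_index` when omitted).
#' @return list with `k` (1-based index of the predicted sample,
#'   `end_index + n_s`) and `y_hat` (predicted mm triple).
#' @export
predict_next <- function(state, series, end_index, config, window = NULL) {
  m <- trace_matrix(series)
  if (is.null(window))
    window <- assemble_window(m, end_index, config$n, config$n_s, config$N_train)
  y_hat <- numeric(3)
  for (a in 1:3) {
    x <- current_regressor(m[, a], end_index, config$n,
                           window$mean[a], window$sd[a])
    y_hat[a] <- unit_forward(state[[a]], x) * window$sd[a] + window$mean[a]
  }
  list(k = end_index + config$n_s, y_hat = y_hat)
}

# Lean retraining loops for the engine hot path. For the in-parameter-
# linear units the Jacobian equals the (expanded) design matrix, constant
# over the window, so LM factorizes once and MLM needs no inversion at all.
retrain_linear <- function(w, J, y, mu, epochs, algorithm) {
  if (algorithm == "lm") {
    R <- chol_damped(crossprod(J), mu)
    for (ep in seq_len(epochs)) {
      e <- y - as.vector(J %*% w)
      w <- w + as.vector(backsolve(R, forwardsolve(t(R), crossprod(J, e))))
    }
  } else {
    d <- colSums(J * J) + 1 / mu
    Jt <- t(J) / d
    for (ep in seq_len(epochs)) {
      e <- y - as.vector(J %*% w)
      w <- w + as.vector(Jt %*% e)
    }
  }
  w
}

retrain_axis <- function(weights, ts, cfg) {
  if (cfg$trainer == "gd") {
    if (cfg$gd_passes >= 1) {
      for (p in seq_len(cfg$gd_passes))
        weights <- gd_pass(weights, ts, cfg$mu, cfg$gd_squared_denominator)
    } else {
      weights <- gd_step(weights, ts$X[ts$N, ], ts$y[ts$N], cfg$mu,
                         cfg$gd_squared_denominator)
    }
    return(weights)
  }
  if (weights$kind %in% c("lnu", "qnu")) {
    J <- if (weights$kind == "qnu") colx_matrix(ts$X) else ts$X
    weights$w <- retrain_linear(weights$w, J, ts$y, cfg$mu,
                                cfg$epochs_retrain, cfg$trainer)
    return(weights)
  }
  # MLP
  if (cfg$trainer == "mlm") {
    prep <- mlm_precompute(weights, ts, cfg$mu)
    for (ep in seq_len(cfg$epochs_retrain))
      weights <- mlm_epoch(weights, ts, cfg$mu, prep)
  } else {
    for (ep in seq_len(cfg$epochs_retrain))
      weights <- lm_epoch(weights, ts, cfg$mu)
  }
  weights
}

init_axis_weights <- function(cfg, axis) {
  init_weights(cfg$predictor, cfg$n, cfg$n1, seed = cfg$seed + axis - 1L)
}

#' Track and predict 3-axis tumor motion online
#'
#' The fitting function of the package: runs the sliding-window real-time
#' prediction engine over a recorded motion trace. One predictor per axis
#' is pretrained on the earliest full window, then, for every subsequent
#' sample, the window slides by one, the predictors are retrained (warm
#' started from the previous weights) and a prediction `n_s` samples ahead
#' is emitted in millimetres. Predictions whose target lies within the
#' trace are paired with the measured values and scored with the 3D error
#' \eqn{e_{3D} = \sqrt{e_1^2 + e_2^2 + e_3^2}}.
#'
#' A transient numerical failure during retraining rolls the weights back
#' to the previous sample's state and prediction continues: the real-time
#' contract is that a prediction is always emitted.
#'
#' @param series a `motion_trace` (or 3-column matrix of mm samples).
#' @param config an [engine_config()]; built from `...` when omitted.
#' @param verbose print a one-line progress summary.
#' @param ... passed to [engine_config()] when `config` is `NULL`.
#' @return a `motion_track` object with components `records` (data frame:
#'   0-based predicted index `k`, time `t`, `y1_hat..y3_hat`, measured
#'   `y1..y3` (NA where the target lies beyond the trace), per-axis errors
#'   and `e3d`), `state` (final per-axis weights), `config`, `pretrain`
#'   (per-axis SSE trajectories), `n_scored`, `sps` and `rollbacks`.
#' @examples
#' tr <- simulate_motion(duration_s = 30, fs = 15, seed = 3)
#' fit <- track_motion(tr, predictor = "lnu", trainer = "lm", n = 15,
#'                     N_train = 45, sampling_hz = 15, n_s = 15,
#'                     epochs_pretrain = 50, epochs_retrain = 2)
#' summary(fit)
#' @export
track_motion <- function(series, config = NULL, verbose = FALSE, ...) {
  if (is.null(config)) config <- engine_config(...)
  if (!inherits(config, "engine_config"))
    stop("config must be an engine_config", call. = FALSE)
  m <- trace_matrix(series)
  fs <- tryCatch(trace_fs(series), error = function(e) config$sampling_hz)
  if (abs(fs - config$sampling_hz) > 1e-9 * fs)
    stop(sprintf("series sampled at %g Hz but engine expects %g Hz; downsample first",
                 fs, config$sampling_hz), call. = FALSE)
  n <- config$n; ns <- config$n_s; N <- config$N_train
  len <- nrow(m)
  e0 <- first_valid_end(n, ns, N)
  if (len < e0)
    stop(sprintf("insufficient history: need %d samples for the first window, trace has %d",
                 e0, len), call. = FALSE)

  state <- lapply(1:3, function(a) init_axis_weights(config, a))

  # pretraining on the earliest full window
  win <- assemble_window(m, e0, n, ns, N)
  pre_cfg <- train_config(config$trainer, config$mu, config$epochs_pretrain,
                          mu_schedule = config$mu_schedule,
                          gd_squared_denominator = config$gd_squared_denominator)
  pretrain <- vector("list", 3)
  for (a in 1:3) {
    res <- train_predictor(state[[a]], win$axes[[a]], pre_cfg)
    state[[a]] <- res$weights
    pretrain[[a]] <- res$q_per_epoch
  }

  nrec <- len - e0 + 1L
  ks <- integer(nrec)
  yh <- matrix(NA_real_, nrec, 3)
  rollbacks <- 0L
  t_start <- proc.time()[["elapsed"]]
  for (r in seq_len(nrec)) {
    end <- e0 + r - 1L
    if (r > 1L) {                     # slide, then retrain before predicting
      win <- assemble_window(m, end, n, ns, N)
      if (config$epochs_retrain > 0L) {
        for (a in 1:3) {
          w0 <- if (config$warm_start) state[[a]] else init_axis_weights(config, a)
          wa <- tryCatch(retrain_axis(w0, win$axes[[a]], config),
                         error = function(e) NULL)
          if (is.null(wa) || !all(is.finite(flatten_weights(wa)))) {
            rollbacks <- rollbacks + 1L   # keep previous sample's weights
          } else state[[a]] <- wa
        }
      }
    }
    p <- predict_next(state, m, end, config, window = win)
    ks[r] <- p$k
    yh[r, ] <- p$y_hat
  }
  elapsed <- proc.time()[["elapsed"]] - t_start

  scored <- ks <= len
  yt <- matrix(NA_real_, nrec, 3)
  yt[scored, ] <- m[ks[scored], , drop = FALSE]
  err <- yt - yh
  rec <- data.frame(k = ks - 1L, t = (ks - 1L) / fs,
                    y1_hat = yh[, 1], y2_hat = yh[, 2], y3_hat = yh[, 3],
                    y1 = yt[, 1], y2 = yt[, 2], y3 = yt[, 3],
                    e1 = err[, 1], e2 = err[, 2], e3 = err[, 3],
                    e3d = sqrt(rowSums(err^2)))
  n_scored <- sum(scored)
  out <- structure(list(records = rec, state = state, config = config,
                        pretrain = pretrain, fs = fs,
                        n_scored = n_scored,
                        sps = if (elapsed > 0) n_scored / elapsed else NA_real_,
                        rollbacks = rollbacks,
                        call = match.call()),
                   class = "motion_track")
  if (verbose) print(out)
  out
}

#' @export
print.motion_track <- function(x, ...) {
  cat(sprintf("online motion tracking fit: %s + %s, %d predictions (%d scored)\n",
              toupper(x$config$predictor), toupper(x$config$trainer),
              nrow(x$records), x$n_scored))
  mae <- mean(x$records$e3d[!is.na(x$records$e3d)])
  cat(sprintf("  3D MAE %.4f mm | horizon %d samples (%.2f s) | ~%.1f samples/s\n",
              mae, x$config$n_s, x$config$n_s / x$fs, x$sps))
  if (x$rollbacks > 0)
    cat(sprintf("  %d retraining rollbacks\n", x$rollbacks))
  invisible(x)
}

#' @export
coef.motion_track <- function(object, ...) object$state

#' @export
residuals.motion_track <- function(object, ...) {
  r <- object$records
  as.matrix(r[!is.na(r$e3d), c("e1", "e2", "e3")])
}

#' @export
fitted.motion_track <- function(object, ...) {
  as.matrix(object$records[, c("y1_hat", "y2_hat", "y3_hat")])
}

#' @export
predict.motion_track <- function(object, newdata, end_index = NULL, ...) {
  m <- trace_matrix(newdata)
  if (is.null(end_index)) end_index <- nrow(m)
  predict_next(object$state, m, end_index, object$config)
}

#' @export
plot.motion_track <- function(x, axis = 2, from_s = NULL, ...) {
  r <- x$records[!is.na(x$records$e3d), ]
  if (!is.null(from_s)) r <- r[r$t >= from_s, ]
  op <- graphics::par(mfrow = c(2, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  yc <- paste0("y", axis); yhc <- paste0("y", axis, "_hat")
  graphics::plot(r$t, r[[yc]], type = "l", xlab = "time [s]",
                 ylab = sprintf("axis %d [mm]", axis), ...)
  graphics::lines(r$t, r[[yhc]], col = 2, lty = 2)
  graphics::legend("topright", c("measured", "predicted"), col = 1:2,
                   lty = 1:2, bty = "n", cex = 0.8)
  graphics::plot(r$t, r$e3d, type = "l", xlab = "time [s]",
                 ylab = "3D error [mm]", ...)
  invisible(x)
}

#' Write per-sample prediction records to CSV
#'
#' Columns `k,y1_hat,y2_hat,y3_hat,y1,y2,y3,e3d` (mm; `k` 0-based).
#'
#' @param fit a `motion_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(fit, path) {
  r <- fit$records[, c("k", "y1_hat", "y2_hat", "y3_hat",
                       "y1", "y2", "y3", "e3d")]
  utils::write.csv(r, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read prediction records written by [write_records_csv()]
#'
#' @param path CSV path.
#' @return data frame of records.
#' @export
read_records_csv <- function(path) {
  r <- utils::read.csv(path)
  need <- c("k", "y1_hat", "y2_hat", "y3_hat", "y1", "y2", "y3", "e3d")
  if (!all(need %in% names(r)))
    stop("records format error: missing columns ",
         paste(setdiff(need, names(r)), collapse = ", "), call. = FALSE)
  r
}
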