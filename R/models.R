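#' Neural unit architectures for motion prediction
#'
#' Three single-output predictors map a short history of one motion axis to
#' a value `n_s` samples ahead:
#' \itemize{
#'   \item LNU (linear neural unit): \eqn{\hat y = w \cdot x}, the linear
#'     baseline, with \eqn{x = (1, y(k), \dots, y(k-n+1))}.
#'   \item QNU (quadratic neural unit): \eqn{\hat y = w \cdot \mathrm{colx}(x)},
#'     a full quadratic form over all products \eqn{x_i x_j}, \eqn{i \le j}.
#'     Nonlinear in the inputs yet linear in the weights, so batch training
#'     is a linear least-squares problem with a unique optimum.
#'   \item MLP: one hidden layer of sigmoidal neurons,
#'     \eqn{\hat y = w_{out} \cdot \phi(W x)} with
#'     \eqn{\phi(v) = 2/(1+e^{-v}) - 1}; no output-neuron bias.
#' }
#'
#' @name architectures
NULL

insufficient_history <- function(need, have) {
  stop(sprintf("insufficient history: regressor needs %d samples, window has %d",
               need, have), call. = FALSE)
}

#' Build the lagged input (regressor) vector
#'
#' Returns \eqn{x = (1, y(k), y(k-1), \dots, y(k-n+1))}: a leading bias
#' term followed by the `n` most recent samples, newest first.
#'
#' @param window numeric vector of samples of one axis, newest last.
#' @param n number of lagged samples (>= 0).
#' @return numeric vector of length `n + 1`, first element 1.
#' @export
build_regressor <- function(window, n) {
  if (n < 0 || n != round(n)) stop("n must be a non-negative integer", call. = FALSE)
  if (length(window) < n) insufficient_history(n, length(window))
  if (n == 0) return(1)
  c(1, rev(window[(length(window) - n + 1):length(window)]))
}

# Cached (i, j) index pairs (1-based columns of x) for the quadratic
# expansion, i <= j in lexicographic order; element 1 pairs the bias with
# itself.
.qnu_index_cache <- new.env(parent = emptyenv())
qnu_index <- function(n) {
  key <- as.character(n)
  hit <- .qnu_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- n + 1L
  ii <- unlist(lapply(seq_len(p), function(i) rep.int(i, p - i + 1L)))
  jj <- unlist(lapply(seq_len(p), function(i) i:p))
  out <- list(i = ii, j = jj)
  .qnu_index_cache[[key]] <- out
  out
}

#' Number of weights of a quadratic neural unit
#'
#' A QNU over `n` lagged inputs (plus bias) has one weight per unordered
#' input pair: \eqn{(n+1)(n+2)/2}.
#'
#' @param n lag count.
#' @return integer weight count.
#' @examples qnu_weight_count(30)  # 496
#' @export
qnu_weight_count <- function(n) as.integer((n + 1) * (n + 2) / 2)

#' Quadratic expansion of a regressor vector
#'
#' All pairwise products \eqn{x_i x_j}, \eqn{0 \le i \le j \le n}, in
#' lexicographic order (`i` outer, `j` inner). The first element is
#' \eqn{x_0^2 = 1}.
#'
#' @param x regressor vector from [build_regressor()].
#' @return numeric vector of length `(n+1)(n+2)/2`.
#' @export
colx <- function(x) {
  idx <- qnu_index(length(x) - 1L)
  x[idx$i] * x[idx$j]
}

# Row-wise quadratic expansion of a regressor matrix (N x (n+1)) into the
# N x m design matrix whose row k is colx(X[k, ]).
colx_matrix <- function(X) {
  idx <- qnu_index(ncol(X) - 1L)
  X[, idx$i, drop = FALSE] * X[, idx$j, drop = FALSE]
}

#' Bipolar sigmoid activation
#'
#' \eqn{\phi(v) = 2/(1 + e^{-v}) - 1 = \tanh(v/2)}, odd and strictly
#' increasing with range (-1, 1).
#'
#' @param v numeric vector.
#' @return numeric vector in (-1, 1).
#' @export
unit_sigmoid <- function(v) 2 / (1 + exp(-v)) - 1

# derivative of unit_sigmoid expressed through its value: (1 - phi^2)/2
unit_sigmoid_deriv <- function(phi) (1 - phi * phi) / 2

new_weights <- function(kind, ...) {
  structure(list(kind = kind, ...), class = c(paste0(kind, "_weights"),
                                              "predictor_weights"))
}

#' Construct predictor weight containers
#'
#' @param w numeric weight vector (`n + 1` for LNU, `(n+1)(n+2)/2` for QNU).
#' @param n lag count.
#' @return a classed weight object.
#' @rdname weights
#' @export
lnu_weights <- function(w, n) {
  if (length(w) != n + 1)
    stop(sprintf("architecture error: LNU with n=%d needs %d weights, got %d",
                 n, n + 1, length(w)), call. = FALSE)
  new_weights("lnu", w = as.numeric(w), n = as.integer(n))
}

#' @rdname weights
#' @export
qnu_weights <- function(w, n) {
  m <- qnu_weight_count(n)
  if (length(w) != m)
    stop(sprintf("architecture error: QNU with n=%d needs %d weights, got %d",
                 n, m, length(w)), call. = FALSE)
  new_weights("qnu", w = as.numeric(w), n = as.integer(n))
}

#' @param W hidden-layer weight matrix, `n1` rows by `n + 1` columns.
#' @param w_out output weight vector of length `n1`.
#' @param n1 hidden-neuron count.
#' @rdname weights
#' @export
mlp_weights <- function(W, w_out, n, n1) {
  W <- as.matrix(W)
  if (!all(dim(W) == c(n1, n + 1)))
    stop(sprintf("architecture error: MLP hidden matrix must be %d x %d, got %d x %d",
                 n1, n + 1, nrow(W), ncol(W)), call. = FALSE)
  if (length(w_out) != n1)
    stop(sprintf("architecture error: MLP output vector must have length %d, got %d",
                 n1, length(w_out)), call. = FALSE)
  if (!all(is.finite(W)) || !all(is.finite(w_out)))
    stop("architecture error: MLP weights must be finite", call. = FALSE)
  new_weights("mlp", W = W, w_out = as.numeric(w_out),
              n = as.integer(n), n1 = as.integer(n1))
}

check_regressor <- function(weights, x) {
  if (length(x) != weights$n + 1)
    stop(sprintf("architecture error: regressor length %d does not match n=%d",
                 length(x), weights$n), call. = FALSE)
}

#' Forward maps of the three architectures
#'
#' `unit_forward()` dispatches on the weight class; the per-architecture
#' functions are exported for direct use.
#'
#' @param weights a weight object from [lnu_weights()], [qnu_weights()],
#'   [mlp_weights()] or [init_weights()].
#' @param x regressor vector (length `n + 1`, leading 1).
#' @return predicted scalar (normalized units).
#' @export
unit_forward <- function(weights, x) UseMethod("unit_forward")

#' @rdname unit_forward
#' @export
unit_forward.lnu_weights <- function(weights, x) lnu_forward(weights, x)

#' @rdname unit_forward
#' @export
unit_forward.qnu_weights <- function(weights, x) qnu_forward(weights, x)

#' @rdname unit_forward
#' @export
unit_forward.mlp_weights <- function(weights, x) mlp_forward(weights, x)

#' @rdname unit_forward
#' @export
lnu_forward <- function(weights, x) {
  check_regressor(weights, x)
  sum(weights$w * x)
}

#' @rdname unit_forward
#' @export
qnu_forward <- function(weights, x) {
  check_regressor(weights, x)
  sum(weights$w * colx(x))
}

#' @rdname unit_forward
#' @export
mlp_forward <- function(weights, x) {
  check_regressor(weights, x)
  sum(weights$w_out * unit_sigmoid(as.vector(weights$W %*% x)))
}

# Batch forward map over a regressor matrix (one row per pattern).
forward_rows <- function(weights, X) {
  switch(weights$kind,
    lnu = as.vector(X %*% weights$w),
    qnu = as.vector(colx_matrix(X) %*% weights$w),
    mlp = as.vector(unit_sigmoid(X %*% t(weights$W)) %*% weights$w_out),
    stop("unknown predictor kind ", weights$kind, call. = FALSE))
}

#' Random initial weights
#'
#' Weights are drawn i.i.d. uniform on \[-0.1, 0.1\] — small enough that
#' MLP hidden neurons start in the quasi-linear region of the sigmoid —
#' under a private seeded stream.
#'
#' @param kind `"lnu"`, `"qnu"` or `"mlp"`.
#' @param n lag count.
#' @param n1 hidden-neuron count (MLP only).
#' @param seed integer seed; same seed, same weights.
#' @return a weight object.
#' @export
init_weights <- function(kind = c("lnu", "qnu", "mlp"), n, n1 = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || n < 0 || n != round(n))
    stop("configuration error: n must be a non-negative integer", call. = FALSE)
  with_seed(seed, switch(kind,
    lnu = lnu_weights(stats::runif(n + 1, -0.1, 0.1), n),
    qnu = qnu_weights(stats::runif(qnu_weight_count(n), -0.1, 0.1), n),
    mlp = {
      if (is.null(n1) || n1 < 1 || n1 != round(n1))
        stop("configuration error: MLP needs a positive integer n1", call. = FALSE)
      mlp_weights(matrix(stats::runif(n1 * (n + 1), -0.1, 0.1), n1, n + 1),
                  stats::runif(n1, -0.1, 0.1), n, n1)
    }))
}

#' @export
print.predictor_weights <- function(x, ...) {
  if (x$kind == "mlp")
    cat(sprintf("MLP weights: n=%d lags, n1=%d hidden neurons (%d weights)\n",
                x$n, x$n1, length(flatten_weights(x))))
  else
    cat(sprintf("%s weights: n=%d lags, %d weights\n", toupper(x$kind), x$n,
                length(x$w)))
  invisible(x)
}

# Flatten weights to a single numeric vector (MLP: hidden rows neuron by
# neuron, then output weights) and back; used by MLM and serialization.
flatten_weights <- function(weights) {
  if (weights$kind == "mlp") c(as.vector(t(weights$W)), weights$w_out)
  else weights$w
}

unflatten_weights <- function(weights, v) {
  if (weights$kind == "mlp") {
    p <- weights$n + 1L
    nh <- weights$n1 * p
    weights$W <- matrix(v[seq_len(nh)], weights$n1, p, byrow = TRUE)
    weights$w_out <- v[nh + seq_len(weights$n1)]
  } else weights$w <- v
  weights
}

#' Serialize predictor weights to JSON
#'
#' The layout records the architecture (`kind`, `n`, `n1`) and the ordered
#' flat weight vector (MLP: hidden neuron rows first, then output weights),
#' making snapshots portable across runs.
#'
#' @param weights a weight object.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string, or `path` invisibly.
#' @export
weights_to_json <- function(weights, path = NULL) {
  obj <- list(kind = weights$kind, n = weights$n,
              n1 = if (weights$kind == "mlp") weights$n1 else NULL,
              w = flatten_weights(weights))
  js <- jsonlite::toJSON(obj[!vapply(obj, is.null, logical(1))],
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Restore predictor weights from JSON
#'
#' @param json JSON string or file path written by [weights_to_json()].
#' @return a weight object.
#' @export
weights_from_json <- function(json) {
  obj <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
         else jsonlite::fromJSON(json)
  switch(obj$kind,
    lnu = lnu_weights(obj$w, obj$n),
    qnu = qnu_weights(obj$w, obj$n),
    mlp = unflatten_weights(mlp_weights(matrix(0, obj$n1, obj$n + 1),
                                        numeric(obj$n1), obj$n, obj$n1), obj$w),
    stop("unknown predictor kind in JSON: ", obj$kind, call. = FALSE))
}
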