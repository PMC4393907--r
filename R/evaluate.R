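#' 3D prediction error
#'
#' Euclidean combination of the three per-axis errors,
#' \eqn{e_{3D} = \sqrt{e_1^2 + e_2^2 + e_3^2}} (mm). Vectorized.
#'
#' @param e1,e2,e3 per-axis errors, mm.
#' @return non-negative scalar (or vector), mm.
#' @examples e3d(3, 4, 0)  # 5
#' @export
e3d <- function(e1, e2, e3) sqrt(e1^2 + e2^2 + e3^2)

#' 3D mean absolute error of a prediction run
#'
#' Averages the per-sample 3D error over the scored records (those whose
#' target was actually measured), optionally restricted to a scoring
#' window. Pretraining samples never appear in the records, so they are
#' excluded by construction.
#'
#' @param records a `motion_track` fit, or its `records` data frame (e.g.
#'   from [read_records_csv()]).
#' @param score_after_s drop records whose target time is below this value
#'   (seconds); with a plain data frame lacking `t`, `fs` is required to
#'   convert the sample index.
#' @param last_s keep only the final `last_s` seconds of scored records.
#' @param fs sampling frequency, needed only when `records` is a plain
#'   data frame without a time column.
#' @return a `motion_eval` list: `mae_mm`, `per_axis_mae_mm`, `n_scored`,
#'   `sps` (NA unless taken from a fit).
#' @export
mae_3d <- function(records, score_after_s = NULL, last_s = NULL, fs = NULL) {
  sps <- NA_real_
  if (inherits(records, "motion_track")) {
    sps <- records$sps
    fs <- records$fs
    records <- records$records
  }
  r <- records
  if (is.null(r$e3d)) stop("records lack an e3d column", call. = FALSE)
  if (is.null(r$t)) {
    if (is.null(fs)) stop("need fs to locate records in time", call. = FALSE)
    r$t <- r$k / fs
  }
  if (is.null(r$e1) && !is.null(r$y1)) {
    r$e1 <- r$y1 - r$y1_hat; r$e2 <- r$y2 - r$y2_hat; r$e3 <- r$y3 - r$y3_hat
  }
  r <- r[!is.na(r$e3d), , drop = FALSE]
  if (!is.null(score_after_s)) r <- r[r$t >= score_after_s, , drop = FALSE]
  if (!is.null(last_s)) r <- r[r$t >= max(r$t) - last_s, , drop = FALSE]
  if (nrow(r) < 1)
    stop("evaluation error: no scored predictions in the scoring window",
         call. = FALSE)
  structure(list(mae_mm = mean(r$e3d),
                 per_axis_mae_mm = c(mean(abs(r$e1)), mean(abs(r$e2)),
                                     mean(abs(r$e3))),
                 n_scored = nrow(r), sps = sps),
            class = "motion_eval")
}

#' @export
print.motion_eval <- function(x, ...) {
  cat(sprintf("3D MAE %.4f mm over %d samples (per-axis %.4f / %.4f / %.4f mm)\n",
              x$mae_mm, x$n_scored, x$per_axis_mae_mm[1],
              x$per_axis_mae_mm[2], x$per_axis_mae_mm[3]))
  if (is.finite(x$sps)) cat(sprintf("  throughput ~%.1f samples/s\n", x$sps))
  invisible(x)
}

#' @export
summary.motion_track <- function(object, score_after_s = NULL, last_s = NULL, ...) {
  out <- mae_3d(object, score_after_s = score_after_s, last_s = last_s)
  out$config <- object$config
  out$rollbacks <- object$rollbacks
  class(out) <- c("summary.motion_track", "motion_eval")
  out
}

#' @export
print.summary.motion_track <- function(x, ...) {
  print(x$config)
  NextMethod()
  invisible(x)
}

#' Aggregate repeated runs started from different initial weights
#'
#' Summarizes the across-repeat distribution of the 3D MAE: minimum, mean
#' and population (ddof 0) standard deviation — the spread across random
#' initial conditions that separates in-parameter-linear units from MLPs.
#'
#' @param reports list of `motion_eval` objects (or numeric MAE vector).
#' @return list with `min_mae_mm`, `mean_mae_mm`, `sigma_mae_mm` (NULL
#'   with fewer than two repeats), `n_repeats`.
#' @export
aggregate_repeats <- function(reports) {
  maes <- if (is.numeric(reports)) reports
          else vapply(reports, function(r) r$mae_mm, numeric(1))
  if (length(maes) < 1) stop("aggregation error: no reports", call. = FALSE)
  sig <- if (length(maes) >= 2)
    sqrt(mean((maes - mean(maes))^2))   # population sd
  else NULL
  list(min_mae_mm = min(maes), mean_mae_mm = mean(maes),
       sigma_mae_mm = sig, n_repeats = length(maes))
}

#' Write an evaluation report as JSON
#'
#' @param report a `motion_eval` (or `summary.motion_track`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(mae_mm = report$mae_mm,
              sigma_mae_mm = report$sigma_mae_mm,
              per_axis_mae_mm = report$per_axis_mae_mm,
              n_scored = report$n_scored, sps = report$sps)
  if (!is.null(report$config)) obj$config <- unclass(report$config)
  jsonlite::write_json(obj[!vapply(obj, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
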