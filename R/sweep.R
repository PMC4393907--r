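#' Specify a configuration-grid sweep
#'
#' Describes the experiment grid over predictor, trainer, sampling rate,
#' lag count `n`, window length `N_train` and (for the MLP) hidden-layer
#' size, each cell repeated from different random initial weights on the
#' same motion trace. The default `n` / `N_train` lists per sampling rate
#' follow the standard grid for the 1 s prediction horizon
#' (`n_s = sampling_hz`).
#'
#' @param trace a [motion_config()] (the trace is generated once), a
#'   `motion_trace`, or a CSV path readable by [read_motion_csv()].
#' @param predictors subset of `c("lnu", "qnu", "mlp")`.
#' @param trainers subset of `c("lm", "mlm", "gd")`; the GD + MLP
#'   combination is rejected at expansion.
#' @param sampling_hz sampling rates to analyze; the trace is decimated to
#'   each.
#' @param n_by_sampling,N_by_sampling named lists mapping sampling rate to
#'   the `n` and `N_train` values tried at that rate.
#' @param n1 hidden-layer sizes (MLP cells only).
#' @param repeats runs per cell with distinct derived seeds.
#' @param master_seed master seed; every cell's seed is derived from it
#'   and the cell description, so results do not depend on execution
#'   order.
#' @param mu,epochs_pretrain,epochs_retrain optional overrides applied to
#'   every cell (trainer defaults otherwise).
#' @return a `sweep_spec`.
#' @export
sweep_spec <- function(trace,
                       predictors = c("lnu", "qnu", "mlp"),
                       trainers = c("lm", "mlm"),
                       sampling_hz = c(15, 30),
                       n_by_sampling = list(`15` = c(15, 30), `30` = c(30, 60)),
                       N_by_sampling = list(`15` = c(180, 270, 360),
                                            `30` = c(90, 135, 180)),
                       n1 = c(1, 2, 3, 5, 7),
                       repeats = 1L, master_seed = 1L,
                       mu = NULL, epochs_pretrain = NULL,
                       epochs_retrain = NULL) {
  predictors <- match.arg(predictors, c("lnu", "qnu", "mlp"), several.ok = TRUE)
  trainers <- match.arg(trainers, c("lm", "mlm", "gd"), several.ok = TRUE)
  if (length(sampling_hz) < 1)
    stop("configuration error: empty sampling grid", call. = FALSE)
  for (s in as.character(sampling_hz)) {
    if (is.null(n_by_sampling[[s]]) || is.null(N_by_sampling[[s]]))
      stop(sprintf("configuration error: no n/N_train grid for sampling %s Hz", s),
           call. = FALSE)
  }
  if (repeats < 1) stop("configuration error: repeats must be >= 1", call. = FALSE)
  structure(list(trace = trace, predictors = predictors, trainers = trainers,
                 sampling_hz = as.numeric(sampling_hz),
                 n_by_sampling = n_by_sampling, N_by_sampling = N_by_sampling,
                 n1 = as.integer(n1), repeats = as.integer(repeats),
                 master_seed = as.integer(master_seed), mu = mu,
                 epochs_pretrain = epochs_pretrain,
                 epochs_retrain = epochs_retrain),
            class = "sweep_spec")
}

# Deterministic 31-bit string hash; cell seeds depend only on the master
# seed and the cell's own description.
cell_seed <- function(master_seed, desc) {
  h <- as.double(master_seed %% 2147483647L)
  for (code in utf8ToInt(desc)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Expand a sweep specification into engine configurations
#'
#' Cartesian expansion of the grid, minus invalid combinations (gradient
#' descent with an MLP), in a fixed deterministic order. Each row carries
#' a seed derived from the master seed and the cell description.
#'
#' @param spec a [sweep_spec()].
#' @return data frame of cells (`predictor`, `trainer`, `sampling_hz`,
#'   `n`, `N_train`, `n1`, `rep`, `seed`, `cell_id`), with rejected cells
#'   and their reasons in `attr(, "rejected")`.
#' @export
expand_sweep <- function(spec) {
  rows <- list(); rej <- list()
  for (pred in spec$predictors) for (trn in spec$trainers) {
    if (pred == "mlp" && trn == "gd") {
      rej[[length(rej) + 1L]] <- data.frame(
        predictor = pred, trainer = trn,
        reason = "gradient-descent adaptation is defined for LNU/QNU only")
      next
    }
    for (sh in spec$sampling_hz) {
      key <- as.character(sh)
      for (n in spec$n_by_sampling[[key]])
        for (N in spec$N_by_sampling[[key]]) {
          n1s <- if (pred == "mlp") spec$n1 else NA_integer_
          for (h1 in n1s) for (r in seq_len(spec$repeats)) {
            desc <- sprintf("%s|%s|%g|%d|%d|%s|rep%d", pred, trn, sh, n, N,
                            ifelse(is.na(h1), "-", h1), r)
            rows[[length(rows) + 1L]] <- data.frame(
              predictor = pred, trainer = trn, sampling_hz = sh,
              n = as.integer(n), N_train = as.integer(N),
              n1 = as.integer(h1), rep = r,
              seed = cell_seed(spec$master_seed, desc),
              cell_id = gsub("[^A-Za-z0-9]+", "_", desc),
              stringsAsFactors = FALSE)
          }
        }
    }
  }
  if (length(rows) == 0)
    stop("configuration error: sweep grid is empty", call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "rejected") <- if (length(rej)) do.call(rbind, rej) else NULL
  out
}

sweep_trace <- function(spec) {
  tr <- spec$trace
  if (inherits(tr, "motion_config")) return(simulate_motion(tr))
  if (inherits(tr, "motion_trace")) return(tr)
  if (is.character(tr)) return(read_motion_csv(tr))
  stop("configuration error: sweep trace must be a motion_config, motion_trace or CSV path",
       call. = FALSE)
}

#' Run a configuration-grid sweep
#'
#' Runs [track_motion()] for every expanded cell on the (decimated) trace,
#' collects per-cell 3D MAE reports and aggregates min / mean / population
#' std of the MAE per predictor-trainer group. Individual cell failures
#' are recorded and the sweep continues. When `out_dir` is given, each
#' finished cell is checkpointed as JSON and completed cells are skipped
#' on rerun.
#'
#' @param spec a [sweep_spec()].
#' @param out_dir optional checkpoint/output directory; results are also
#'   written there as `sweep_results.csv` and `sweep_summary.json`.
#' @param score_after_s optional scoring-window start passed to [mae_3d()].
#' @param verbose print one line per cell.
#' @return a `motion_sweep`: list with `results` (one row per cell),
#'   `summary` (per-group aggregates) and `rejected`.
#' @export
run_sweep <- function(spec, out_dir = NULL, score_after_s = NULL,
                      verbose = FALSE) {
  cells <- expand_sweep(spec)
  base <- sweep_trace(spec)
  base_fs <- trace_fs(base)
  traces <- list()
  for (sh in unique(cells$sampling_hz)) {
    fac <- base_fs / sh
    if (abs(fac - round(fac)) > 1e-9)
      stop(sprintf("configuration error: trace at %g Hz cannot be decimated to %g Hz",
                   base_fs, sh), call. = FALSE)
    traces[[as.character(sh)]] <- downsample_motion(base, round(fac))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  res <- cells
  res$mae_mm <- res$mae_y1 <- res$mae_y2 <- res$mae_y3 <- NA_real_
  res$sps <- NA_real_
  res$error <- NA_character_
  for (i in seq_len(nrow(cells))) {
    ck <- if (!is.null(out_dir))
      file.path(out_dir, paste0("cell_", cells$cell_id[i], ".json")) else NULL
    if (!is.null(ck) && file.exists(ck)) {
      got <- jsonlite::read_json(ck, simplifyVector = TRUE)
      res$mae_mm[i] <- got$mae_mm
      res$mae_y1[i] <- got$per_axis_mae_mm[1]
      res$mae_y2[i] <- got$per_axis_mae_mm[2]
      res$mae_y3[i] <- got$per_axis_mae_mm[3]
      res$sps[i] <- got$sps
      next
    }
    cfg <- engine_config(predictor = cells$predictor[i],
                         trainer = cells$trainer[i],
                         n = cells$n[i], n_s = round(cells$sampling_hz[i]),
                         N_train = cells$N_train[i],
                         sampling_hz = cells$sampling_hz[i],
                         n1 = if (is.na(cells$n1[i])) NULL else cells$n1[i],
                         mu = spec$mu,
                         epochs_pretrain = spec$epochs_pretrain,
                         epochs_retrain = spec$epochs_retrain,
                         seed = cells$seed[i])
    ev <- tryCatch({
      fit <- track_motion(traces[[as.character(cells$sampling_hz[i])]], cfg)
      mae_3d(fit, score_after_s = score_after_s)
    }, error = function(e) e)
    if (inherits(ev, "error")) {
      res$error[i] <- conditionMessage(ev)
      if (verbose) message(sprintf("[%d/%d] %s FAILED: %s", i, nrow(cells),
                                   cells$cell_id[i], res$error[i]))
      next
    }
    res$mae_mm[i] <- ev$mae_mm
    res$mae_y1[i] <- ev$per_axis_mae_mm[1]
    res$mae_y2[i] <- ev$per_axis_mae_mm[2]
    res$mae_y3[i] <- ev$per_axis_mae_mm[3]
    res$sps[i] <- ev$sps
    if (!is.null(ck)) write_report_json(ev, ck)
    if (verbose) message(sprintf("[%d/%d] %s MAE %.3f mm", i, nrow(cells),
                                 cells$cell_id[i], ev$mae_mm))
  }

  groups <- unique(res[, c("predictor", "trainer")])
  summ <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- res$predictor == groups$predictor[g] &
      res$trainer == groups$trainer[g] & !is.na(res$mae_mm)
    maes <- res$mae_mm[sel]
    agg <- if (length(maes)) aggregate_repeats(maes)
           else list(min_mae_mm = NA, mean_mae_mm = NA, sigma_mae_mm = NA)
    data.frame(predictor = groups$predictor[g], trainer = groups$trainer[g],
               n_runs = length(maes), min_mae_mm = agg$min_mae_mm,
               mean_mae_mm = agg$mean_mae_mm,
               sigma_mae_mm = ifelse(is.null(agg$sigma_mae_mm), NA,
                                     agg$sigma_mae_mm))
  }))
  out <- structure(list(results = res, summary = summ,
                        rejected = attr(cells, "rejected")),
                   class = "motion_sweep")
  if (!is.null(out_dir)) {
    utils::write.csv(res, file.path(out_dir, "sweep_results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(out_dir, "sweep_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' @export
print.motion_sweep <- function(x, ...) {
  cat(sprintf("sweep: %d cells (%d failed)\n", nrow(x$results),
              sum(!is.na(x$results$error))))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$rejected)) {
    cat("rejected combinations:\n")
    print(x$rejected, row.names = FALSE)
  }
  invisible(x)
}

#' Read a sweep specification from YAML or JSON
#'
#' The file mirrors [sweep_spec()]; the trace is given either as
#' `trace: {csv: path}` or `trace: {generator: {...motion_config...}}`.
#'
#' @param path YAML or JSON file.
#' @return a `sweep_spec`.
#' @export
read_sweep_spec <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- cfg$trace
  trace <- if (!is.null(tr$csv)) tr$csv
           else if (!is.null(tr$generator)) do.call(motion_config, tr$generator)
           else stop("configuration error: sweep trace must give 'csv' or 'generator'",
                     call. = FALSE)
  cfg$trace <- NULL
  args <- c(list(trace = trace), cfg)
  do.call(sweep_spec, args)
}
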