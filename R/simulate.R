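#' Configuration for the synthetic breathing-motion generator
#'
#' Builds and validates the parameter set of [simulate_motion()]. The
#' generator emulates quasiperiodic thoracic tumor motion: a dominant
#' breathing period drifting around 3 s, per-axis amplitudes of a few
#' millimetres to a couple of centimetres, slowly varying baseline,
#' additive measurement noise, and optional abrupt non-respiratory
#' ("unexpected move") displacements.
#'
#' @param duration_s trace length in seconds (> 0).
#' @param fs sampling frequency in Hz (default 30, the usual fluoroscopic
#'   marker-tracking rate).
#' @param base_period_s nominal breathing period in seconds (default 3).
#' @param period_drift standard deviation, per square-root second, of the
#'   random walk on the log instantaneous period. 0 freezes the period.
#' @param amplitude_mm numeric triple: base half-amplitude of each axis
#'   (lateral, cephalocaudal, anteroposterior) in mm.
#' @param amplitude_drift standard deviation, per square-root second, of the
#'   random walk on each axis' log amplitude. 0 freezes the amplitudes.
#' @param baseline_drift_mm_per_s standard deviation, per square-root
#'   second, of the random walk on each axis' baseline (mm).
#' @param noise_std_mm standard deviation of additive white measurement
#'   noise in mm (>= 0).
#' @param waveform_power even integer >= 2 shaping the breathing waveform
#'   \eqn{w(\phi) = 2\cos^p(\phi/2) - 1}. Power 2 gives a pure sinusoid;
#'   larger powers give the flat-exhale / sharp-inhale asymmetry of real
#'   breathing.
#' @param unexpected_moves list of moves, each a list with elements
#'   `time_s` (onset), `offset_mm` (numeric triple) and `ramp_s`
#'   (rise time; 0 = step). The offset is reached smoothly and persists.
#' @param seed integer RNG seed; identical configurations (including seed)
#'   generate bit-identical traces.
#'
#' @return an object of class `motion_config`.
#' @seealso [simulate_motion()]
#' @export
motion_config <- function(duration_s,
                          fs = 30,
                          base_period_s = 3,
                          period_drift = 0.02,
                          amplitude_mm = c(4, 10, 6),
                          amplitude_drift = 0.03,
                          baseline_drift_mm_per_s = 0.05,
                          noise_std_mm = 0.05,
                          waveform_power = 4,
                          unexpected_moves = list(),
                          seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid generator configuration: field '%s' %s",
                          field, msg), call. = FALSE)
  }
  chk(is.numeric(duration_s) && length(duration_s) == 1 && duration_s > 0,
      "duration_s", "must be a positive number")
  chk(is.numeric(fs) && length(fs) == 1 && fs > 0, "fs",
      "must be a positive number")
  chk(is.numeric(base_period_s) && length(base_period_s) == 1 &&
        base_period_s > 0, "base_period_s", "must be a positive number")
  chk(is.numeric(period_drift) && length(period_drift) == 1 &&
        period_drift >= 0, "period_drift", "must be >= 0")
  chk(is.numeric(amplitude_mm) && length(amplitude_mm) == 3 &&
        all(amplitude_mm >= 0), "amplitude_mm",
      "must be a non-negative numeric triple")
  chk(is.numeric(amplitude_drift) && length(amplitude_drift) == 1 &&
        amplitude_drift >= 0, "amplitude_drift", "must be >= 0")
  chk(is.numeric(baseline_drift_mm_per_s) &&
        length(baseline_drift_mm_per_s) == 1 && baseline_drift_mm_per_s >= 0,
      "baseline_drift_mm_per_s", "must be >= 0")
  chk(is.numeric(noise_std_mm) && length(noise_std_mm) == 1 &&
        noise_std_mm >= 0, "noise_std_mm", "must be >= 0")
  chk(is.numeric(waveform_power) && length(waveform_power) == 1 &&
        waveform_power >= 2 && waveform_power %% 2 == 0,
      "waveform_power", "must be an even integer >= 2")
  chk(is.list(unexpected_moves), "unexpected_moves", "must be a list")
  for (mv in unexpected_moves) {
    chk(is.list(mv) && all(c("time_s", "offset_mm", "ramp_s") %in% names(mv)),
        "unexpected_moves",
        "entries need elements time_s, offset_mm, ramp_s")
    chk(length(mv$offset_mm) == 3, "unexpected_moves",
        "offset_mm must be a numeric triple")
    chk(mv$ramp_s >= 0, "unexpected_moves", "ramp_s must be >= 0")
  }
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed",
      "must be a finite integer")
  structure(list(
    duration_s = as.numeric(duration_s), fs = as.numeric(fs),
    base_period_s = as.numeric(base_period_s),
    period_drift = as.numeric(period_drift),
    amplitude_mm = as.numeric(amplitude_mm),
    amplitude_drift = as.numeric(amplitude_drift),
    baseline_drift_mm_per_s = as.numeric(baseline_drift_mm_per_s),
    noise_std_mm = as.numeric(noise_std_mm),
    waveform_power = as.integer(waveform_power),
    unexpected_moves = unexpected_moves,
    seed = as.integer(seed)),
    class = "motion_config")
}

# Run code under a private RNG stream without disturbing the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fold a random walk back into [lo, hi] (triangle-wave reflection), keeping
# slow drifts bounded around the base value.
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep(lo, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate a synthetic 3-axis tumor motion trace
#'
#' Phase-oscillator model of breathing motion: each axis is
#' \eqn{b_a(t) + A_a(t)\, w(\phi(t)) + \epsilon}, where the phase advances
#' by \eqn{2\pi/(\mathrm{period}(t) f_s)} per sample, the instantaneous
#' period and per-axis amplitudes follow bounded slow random walks around
#' their base values (period within 0.5-1.5x, amplitude within 0.5-1.5x),
#' and \eqn{w} is a raised cosine to an even power. The three axes share
#' the breathing phase but have independent amplitudes, baselines and
#' noise. Unexpected moves add a smooth-step offset per axis.
#'
#' All randomness comes from one seeded stream drawn in a fixed order
#' (period walk, then per-axis amplitude walks, baseline walks, noise), so
#' a configuration is bit-reproducible across calls and platforms.
#'
#' @param config a [motion_config()], or `NULL` to build one from `...`.
#' @param ... passed to [motion_config()] when `config` is `NULL`.
#' @return a `motion_trace`: a data frame with columns `t` (s) and `y1`,
#'   `y2`, `y3` (mm), and attributes `fs` (Hz) and `t0`.
#' @examples
#' tr <- simulate_motion(duration_s = 20, seed = 7)
#' range(tr$y2)
#' @export
simulate_motion <- function(config = NULL, ...) {
  if (is.null(config)) config <- motion_config(...)
  if (!inherits(config, "motion_config"))
    stop("invalid generator configuration: expected a 'motion_config' object",
         call. = FALSE)
  nk <- round(config$duration_s * config$fs)
  if (nk < 1)
    stop("invalid generator configuration: field 'duration_s' too short for one sample",
         call. = FALSE)
  fs <- config$fs
  step_sd <- 1 / sqrt(fs)   # per-sample sd scaling for per-sqrt(second) rates

  with_seed(config$seed, {
    # 1. instantaneous period: bounded random walk on log period
    if (config$period_drift > 0) {
      lp <- cumsum(c(0, stats::rnorm(nk - 1, 0, config$period_drift * step_sd)))
      lp <- reflect_into(lp, log(0.5), log(1.5))
    } else lp <- numeric(nk)
    period <- config$base_period_s * exp(lp)

    # 2. per-axis amplitude walks (log scale, bounded)
    amp <- matrix(0, nk, 3)
    for (a in 1:3) {
      if (config$amplitude_drift > 0) {
        la <- cumsum(c(0, stats::rnorm(nk - 1, 0, config$amplitude_drift * step_sd)))
        la <- reflect_into(la, log(0.5), log(1.5))
      } else la <- numeric(nk)
      amp[, a] <- config$amplitude_mm[a] * exp(la)
    }

    # 3. per-axis baseline walks
    base <- matrix(0, nk, 3)
    for (a in 1:3) {
      if (config$baseline_drift_mm_per_s > 0)
        base[, a] <- cumsum(c(0, stats::rnorm(nk - 1, 0,
                                config$baseline_drift_mm_per_s * step_sd)))
    }

    # 4. measurement noise
    noise <- if (config$noise_std_mm > 0)
      matrix(stats::rnorm(nk * 3, 0, config$noise_std_mm), nk, 3)
    else matrix(0, nk, 3)

    phase <- cumsum(c(0, 2 * pi / (period[-nk] * fs)))
    # raised cosine to an even power, rescaled to [-1, 1]; power 2 is cos(phase)
    w <- 2 * cos(phase / 2)^config$waveform_power - 1

    t <- (seq_len(nk) - 1) / fs
    y <- base + amp * w + noise
    for (mv in config$unexpected_moves) {
      u <- pmin(pmax((t - mv$time_s) / max(mv$ramp_s, 1 / fs), 0), 1)
      s <- u * u * (3 - 2 * u)   # smoothstep ramp
      y <- y + outer(s, as.numeric(mv$offset_mm))
    }
    as_motion_trace(y, fs = fs, t0 = 0)
  })
}

#' Construct a motion trace from raw samples
#'
#' @param y numeric matrix or data frame with 3 columns (mm), one row per
#'   sample.
#' @param fs sampling frequency, Hz.
#' @param t0 time of the first sample, s.
#' @return a `motion_trace` data frame (`t`, `y1`, `y2`, `y3`).
#' @export
as_motion_trace <- function(y, fs, t0 = 0) {
  y <- as.matrix(y)
  if (ncol(y) != 3) stop("motion trace needs exactly 3 axis columns", call. = FALSE)
  if (nrow(y) < 1) stop("motion trace needs at least one sample", call. = FALSE)
  if (!all(is.finite(y))) stop("motion trace samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive number", call. = FALSE)
  out <- data.frame(t = t0 + (seq_len(nrow(y)) - 1) / fs,
                    y1 = y[, 1], y2 = y[, 2], y3 = y[, 3])
  attr(out, "fs") <- fs
  attr(out, "t0") <- t0
  class(out) <- c("motion_trace", "data.frame")
  out
}

#' @export
print.motion_trace <- function(x, ...) {
  fs <- attr(x, "fs")
  cat(sprintf("3-axis motion trace: %d samples at %g Hz (%.2f s)\n",
              nrow(x), fs, nrow(x) / fs))
  rng <- vapply(x[c("y1", "y2", "y3")], range, numeric(2))
  cat(sprintf("  axis ranges [mm]: y1 [%.2f, %.2f]  y2 [%.2f, %.2f]  y3 [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' @export
plot.motion_trace <- function(x, axes = 1:3, ...) {
  op <- graphics::par(mfrow = c(length(axes), 1), mar = c(3.5, 4, 1, 1))
  on.exit(graphics::par(op))
  labs <- c("lateral y1 [mm]", "cephalocaudal y2 [mm]", "anteroposterior y3 [mm]")
  for (a in axes) {
    graphics::plot(x$t, x[[paste0("y", a)]], type = "l", xlab = "time [s]",
                   ylab = labs[a], ...)
  }
  invisible(x)
}

trace_matrix <- function(series) {
  if (inherits(series, "motion_trace") || is.data.frame(series))
    as.matrix(series[, c("y1", "y2", "y3")])
  else as.matrix(series)
}

trace_fs <- function(series, sampling_hz = NULL) {
  fs <- attr(series, "fs")
  if (is.null(fs)) fs <- sampling_hz
  if (is.null(fs)) stop("sampling frequency unknown; supply sampling_hz", call. = FALSE)
  fs
}

#' Write a motion trace to CSV
#'
#' Full-precision CSV with header `t,y1,y2,y3` (time in seconds, positions
#' in mm) or `k,y1,y2,y3` (0-based sample index).
#'
#' @param series a `motion_trace`.
#' @param path output file path.
#' @param time_column `"t"` (seconds, default) or `"k"` (0-based index).
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(series, path, time_column = c("t", "k")) {
  time_column <- match.arg(time_column)
  fs <- trace_fs(series)
  m <- trace_matrix(series)
  tc <- if (time_column == "t") sprintf("%.17g", series$t)
        else as.character(seq_len(nrow(m)) - 1L)
  lines <- paste(tc,
                 sprintf("%.17g", m[, 1]),
                 sprintf("%.17g", m[, 2]),
                 sprintf("%.17g", m[, 3]), sep = ",")
  writeLines(c(paste0(time_column, ",y1,y2,y3"), lines), path)
  invisible(path)
}

#' Read a motion trace from CSV
#'
#' Accepts the format written by [write_motion_csv()]: a header line
#' `t,y1,y2,y3` or `k,y1,y2,y3` followed by numeric rows. With a time
#' column, the sampling rate is inferred from the median time step and the
#' steps must be uniform (jitter below 10% of the step); with an index
#' column `fs` must be supplied.
#'
#' @param path CSV file path.
#' @param fs sampling frequency in Hz; required for `k`-indexed files,
#'   overrides inference otherwise.
#' @return a `motion_trace`.
#' @export
read_motion_csv <- function(path, fs = NULL) {
  ferr <- function(line, msg)
    stop(sprintf("trace format error (%s, line %d): %s", basename(path), line, msg),
         call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) != 4)
    ferr(1, sprintf("expected 4 columns (t|k,y1,y2,y3), found %d", ncol(df)))
  if (!(names(df)[1] %in% c("t", "k")) ||
      !identical(names(df)[2:4], c("y1", "y2", "y3")))
    ferr(1, sprintf("expected header 't,y1,y2,y3' or 'k,y1,y2,y3', found '%s'",
                    paste(names(df), collapse = ",")))
  for (j in 1:4) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      ferr(bad[1] + 1L, sprintf("non-numeric value '%s' in column '%s'",
                                as.character(df[[j]][bad[1]]), names(df)[j]))
    df[[j]] <- v
  }
  if (nrow(df) < 1) ferr(2, "no samples")
  if (names(df)[1] == "k") {
    if (is.null(fs))
      stop("trace format error: index-based CSV needs an explicit fs", call. = FALSE)
    t0 <- df$k[1] / fs
  } else {
    tt <- df$t
    if (nrow(df) >= 2) {
      dt <- diff(tt)
      step <- stats::median(dt)
      if (step <= 0) ferr(which(dt <= 0)[1] + 2L, "time column not increasing")
      bad <- which(abs(dt - step) > 0.1 * step)
      if (length(bad) > 0)
        ferr(bad[1] + 2L,
             sprintf("non-uniform time step %.6g (expected %.6g +/- 10%%)",
                     dt[bad[1]], step))
      inferred <- 1 / step
      if (is.null(fs)) fs <- inferred
    } else if (is.null(fs)) {
      stop("trace format error: single-row CSV needs an explicit fs", call. = FALSE)
    }
    t0 <- tt[1]
  }
  as_motion_trace(as.matrix(df[, c("y1", "y2", "y3")]), fs = fs, t0 = t0)
}

#' Downsample a motion trace by decimation
#'
#' Keeps every `factor`-th sample starting at the first one and divides the
#' sampling frequency accordingly. No anti-alias filter is applied: the
#' dominant breathing band (around 1/3 Hz) lies far below the decimated
#' Nyquist frequency for the factors of interest (30 to 15 Hz).
#'
#' @param series a `motion_trace`.
#' @param factor positive integer decimation factor.
#' @return a `motion_trace` at `fs/factor`.
#' @export
downsample_motion <- function(series, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1 ||
      factor != round(factor))
    stop("downsampling factor must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(series)
  fs <- trace_fs(series)
  keep <- seq(1L, nrow(series), by = factor)
  as_motion_trace(trace_matrix(series)[keep, , drop = FALSE],
                  fs = fs / factor, t0 = attr(series, "t0"))
}

#' Read a generator configuration from YAML or JSON
#'
#' The file mirrors the arguments of [motion_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `motion_config`.
#' @export
read_motion_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$unexpected_moves) && length(cfg$unexpected_moves) == 0)
    cfg$unexpected_moves <- list()
  do.call(motion_config, cfg)
}
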