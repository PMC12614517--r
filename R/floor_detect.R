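#' Maximum signal-to-noise ratio series
#'
#' Aggregates all sensors into a single detection statistic. Per sensor, the
#' mean signal power (acceleration squared) is computed in consecutive
#' non-overlapping windows of `window_s` seconds and divided by that
#' sensor's own median window power, which puts every sensor on a common
#' SNR scale regardless of gain or distance-dependent sensitivity (any
#' positive per-channel gain cancels). The series `snr_max` is the
#' per-window maximum across sensors.
#'
#' @param record A preprocessed, synchronized [vibration_record()].
#' @param window_s Window length in seconds (default 0.02 s).
#' @return Tibble of class `snr_series` with `window_time_s` (window
#'   centers) and `snr_max`; the per-sensor SNR matrix is kept in
#'   `attr(., "per_sensor")` and the window length in `attr(., "window_s")`.
#' @export
snr_max <- function(record, window_s = 0.02) {
  fs <- record$sample_rate
  nw <- max(1L, round(window_s * fs))
  n <- nrow(record$data)
  n_win <- n %/% nw
  if (n_win < 1) abort("record shorter than one window")
  per_sensor <- vapply(record$data, function(x) {
    p <- colMeans(matrix(x[seq_len(n_win * nw)]^2, nrow = nw))
    m <- median(p)
    if (m <= 0) abort("degenerate channel: median window power is zero")
    p / m
  }, numeric(n_win))
  out <- tibble(
    window_time_s = (seq_len(n_win) - 0.5) * nw / fs,
    snr_max = do.call(pmax, as.data.frame(per_sensor))
  )
  attr(out, "per_sensor") <- per_sensor
  attr(out, "window_s") <- nw / fs
  class(out) <- c("snr_series", class(out))
  out
}

#' Detect footsteps from the SNR-max series
#'
#' Adaptive peak detection. The noise scale `sigma_snr` is the standard
#' deviation of `snr_max` after excluding points more than `mad_cut` raw
#' median absolute deviations above the median (a one-sided exclusion: the
#' footstep peaks themselves are positive excursions and must not inflate
#' the noise estimate). Peaks are local maxima at least
#' `median(snr_max) + k_sigma * sigma_snr` high, thinned greedily
#' highest-first so that retained peaks are at least `min_dist_s` apart.
#'
#' @param snr An `snr_series` from [snr_max()].
#' @param k_sigma Peak height threshold in noise SDs above the median.
#' @param mad_cut Exclusion threshold (raw MADs above the median) for the
#'   noise-SD estimate.
#' @param min_dist_s Minimum spacing between retained peaks, seconds.
#' @return Tibble of class `step_series` with `step_time_s` (ascending) and
#'   `snr`; detection parameters are kept as attributes (`threshold`,
#'   `sigma_snr`, `window_s`).
#' @export
detect_steps <- function(snr, k_sigma = 9, mad_cut = 3, min_dist_s = 0.3) {
  x <- snr$snr_max
  med <- median(x)
  raw_mad <- mad(x, constant = 1)
  keep <- x <= med + mad_cut * raw_mad
  sigma_snr <- sd(x[keep])
  if (!is.finite(sigma_snr) || sigma_snr == 0) {
    abort("degenerate SNR series: zero noise spread")
  }
  threshold <- med + k_sigma * sigma_snr

  n <- length(x)
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n], FALSE) &
    x >= threshold
  cand <- which(is_peak)
  # greedy highest-first minimum-distance suppression
  cand <- cand[order(x[cand], decreasing = TRUE)]
  t_cand <- snr$window_time_s[cand]
  kept_t <- numeric(0)
  kept_i <- integer(0)
  for (j in seq_along(cand)) {
    if (!length(kept_t) || all(abs(t_cand[j] - kept_t) >= min_dist_s)) {
      kept_t <- c(kept_t, t_cand[j])
      kept_i <- c(kept_i, cand[j])
    }
  }
  o <- order(kept_t)
  out <- tibble(step_time_s = kept_t[o], snr = x[kept_i[o]])
  attr(out, "threshold") <- threshold
  attr(out, "sigma_snr") <- sigma_snr
  attr(out, "window_s") <- attr(snr, "window_s")
  class(out) <- c("step_series", class(out))
  out
}

#' Cadence from detected step times
#'
#' Computes the inter-step intervals and removes outliers — missed steps or
#' pauses appear as abnormally long intervals — before converting the mean
#' interval to steps per minute. Outliers are intervals outside the median
#' plus/minus `mad_cut` raw MADs; when the MAD is zero (perfectly periodic
#' steps) intervals longer than 1.5 times the median are removed instead.
#'
#' @param steps A `step_series` from [detect_steps()] with at least 4 steps.
#' @param mad_cut Outlier cut in raw MADs around the median interval.
#' @return List of class `floor_cadence`: `cadence_spm`, `n_intervals_used`,
#'   `n_removed`, `n_missed` (removed long intervals, a missed-step proxy),
#'   and the interval tibble.
#' @export
cadence_from_steps <- function(steps, mad_cut = 3) {
  if (nrow(steps) < 4) abort("need at least 4 detected steps")
  dt <- diff(steps$step_time_s)
  med <- median(dt)
  raw_mad <- mad(dt, constant = 1)
  if (raw_mad > 0) {
    keep <- abs(dt - med) <= mad_cut * raw_mad
  } else {
    keep <- dt <= 1.5 * med
  }
  if (!any(keep)) abort("all inter-step intervals removed as outliers")
  structure(
    list(cadence_spm = 60 / mean(dt[keep]),
         n_intervals_used = sum(keep), n_removed = sum(!keep),
         n_missed = sum(!keep & dt > med),
         intervals = tibble(dt_s = dt, kept = keep)),
    class = "floor_cadence"
  )
}

#' @export
print.floor_cadence <- function(x, ...) {
  cat(sprintf("<floor_cadence> %.1f steps/min (%d intervals, %d outliers removed)\n",
              x$cadence_spm, x$n_intervals_used, x$n_removed))
  invisible(x)
}

#' Z-scored instantaneous cadence per step interval
#'
#' The instantaneous cadence of each inter-step interval (60 / interval) is
#' standardized by the trial mean and SD. Missed steps double the interval
#' and show up as precipitous negative z-scores, which makes this a
#' per-trial detection-quality diagnostic.
#'
#' @param steps A `step_series` with at least 3 steps.
#' @return Tibble with `gap`, `dt_s`, `inst_cadence_spm`, `z`.
#' @export
instantaneous_cadence_z <- function(steps) {
  if (nrow(steps) < 3) abort("need at least 3 steps (2 intervals)")
  dt <- diff(steps$step_time_s)
  c_inst <- 60 / dt
  s <- sd(c_inst)
  if (!is.finite(s) || s == 0) {
    abort("zero variance in instantaneous cadence (perfectly periodic steps)")
  }
  tibble(gap = seq_along(dt), dt_s = dt, inst_cadence_spm = c_inst,
         z = (c_inst - mean(c_inst)) / s)
}
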