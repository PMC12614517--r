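#' Foot-swing signal
#'
#' The foot-swing signal for one side is the 3-D distance between that ankle
#' and the pelvis. Because both joints ride the walker's translation, the
#' distance cancels forward motion and oscillates at the *stride* frequency
#' (one stride = two steps), which is what makes it usable for cadence.
#' Frames where either joint dropped out are `NA`; short gaps are
#' interpolated downstream when the signal is resampled.
#'
#' @param stream A [joint_stream()] containing pelvis and both ankles.
#' @param min_coverage Minimum fraction of frames on which pelvis and both
#'   ankles must be tracked.
#' @return A tibble of class `foot_swing` with `time_s`, `fs_left_m`,
#'   `fs_right_m`.
#' @export
foot_swing <- function(stream, min_coverage = 0.5) {
  pelvis <- joint_xyz(stream, "pelvis")
  la <- joint_xyz(stream, "ankle_left")
  ra <- joint_xyz(stream, "ankle_right")
  fs <- function(a) sqrt(rowSums((a - pelvis)^2))
  out <- tibble(time_s = stream$time_s, fs_left_m = fs(la), fs_right_m = fs(ra))
  coverage <- mean(!is.na(out$fs_left_m) & !is.na(out$fs_right_m))
  if (coverage < min_coverage) {
    abort(sprintf(
      "pelvis and ankles jointly tracked on %.0f%% of frames; need >= %.0f%%",
      100 * coverage, 100 * min_coverage))
  }
  class(out) <- c("foot_swing", class(out))
  out
}

#' Cadence from the foot-swing spectrum
#'
#' Each side's foot-swing signal is mean-removed, resampled to a uniform
#' grid at the median frame rate (camera timestamps jitter around the
#' nominal rate), zero-padded for fine frequency resolution, and Fourier
#' transformed. The per-side dominant frequency within `band_hz` is the
#' stride frequency; cadence in steps per minute is
#' `120 * mean(f_max_left, f_max_right)` since each stride contains two
#' steps. Ties in spectral magnitude break toward the lowest frequency.
#'
#' @param fs A [foot_swing()] tibble.
#' @param band_hz Search band (Hz) for the stride frequency. The default
#'   0.5–1.5 Hz spans 60–180 steps/min.
#' @param pad_s Zero-padded signal length in seconds; 100 s gives a
#'   frequency grid no coarser than 0.01 Hz (1.2 steps/min).
#' @return List of class `cadence_fft`: `cadence_spm`, `f_max_left_hz`,
#'   `f_max_right_hz`, `resolution_hz`, and per-side spectra for plotting.
#' @export
cadence_fft <- function(fs, band_hz = c(0.5, 1.5), pad_s = 100) {
  if (length(band_hz) != 2 || band_hz[2] <= band_hz[1] || band_hz[1] < 0) {
    abort("band_hz must be an increasing (low, high) pair")
  }
  sides <- lapply(list(left = fs$fs_left_m, right = fs$fs_right_m),
                  side_peak_freq, time_s = fs$time_s,
                  band_hz = band_hz, pad_s = pad_s)
  cad <- 120 * mean(c(sides$left$f_max, sides$right$f_max))
  structure(
    list(cadence_spm = cad,
         f_max_left_hz = sides$left$f_max, f_max_right_hz = sides$right$f_max,
         resolution_hz = sides$left$resolution_hz,
         spectra = dplyr::bind_rows(
           tibble(side = "left", freq_hz = sides$left$freq, mag = sides$left$mag),
           tibble(side = "right", freq_hz = sides$right$freq, mag = sides$right$mag))),
    class = "cadence_fft"
  )
}

side_peak_freq <- function(x, time_s, band_hz, pad_s) {
  ok <- !is.na(x)
  if (sum(ok) < 3 || diff(range(time_s[ok])) < 3) {
    abort("need at least 3 s of tracked foot-swing signal per side")
  }
  dt <- median(diff(time_s[ok]))
  grid <- seq(min(time_s[ok]), max(time_s[ok]), by = dt)
  xg <- approx(time_s[ok], x[ok], xout = grid, method = "linear")$y
  xg <- xg - mean(xg)
  n_pad <- max(length(xg), nextn(ceiling(pad_s / dt), 2))
  spec <- Mod(fft(c(xg, numeric(n_pad - length(xg)))))
  freq <- (seq_len(n_pad) - 1) / (n_pad * dt)
  in_band <- freq >= band_hz[1] & freq <= band_hz[2]
  if (!any(in_band)) abort("empty frequency search band")
  f_band <- freq[in_band]
  m_band <- spec[in_band]
  list(f_max = f_band[which.max(m_band)], resolution_hz = 1 / (n_pad * dt),
       freq = f_band, mag = m_band)
}

#' @export
print.cadence_fft <- function(x, ...) {
  cat(sprintf(
    "<cadence_fft> %.1f steps/min (stride %.3f / %.3f Hz, grid %.4f Hz)\n",
    x$cadence_spm, x$f_max_left_hz, x$f_max_right_hz, x$resolution_hz))
  invisible(x)
}
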