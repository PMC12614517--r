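#' Per-trial gait metrics from a skeleton stream
#'
#' Runs the full camera pipeline: pelvis displacement, dropout cleaning,
#' trimmed linear speed fit, and FFT foot-swing cadence. Failures are
#' reported through `quality_flag` rather than errors so that batch
#' processing of trials can proceed.
#'
#' @param stream A [joint_stream()].
#' @param r2_threshold,min_points Passed to [fit_gait_speed()].
#' @param band_hz Passed to [cadence_fft()].
#' @return One-row tibble: `speed_m_s`, `cadence_spm`, `speed_r2`,
#'   `trimmed_fraction`, `quality_flag` (`ok` / `trim_failed`), `source`.
#' @export
kinect_gait_metrics <- function(stream, r2_threshold = 0.98, min_points = 30,
                                band_hz = c(0.5, 1.5)) {
  fit <- clean_distance(pelvis_distance(stream))
  n_clean <- nrow(fit)
  fit <- fit_gait_speed(fit, r2_threshold = r2_threshold,
                        min_points = min_points)
  cad <- cadence_fft(foot_swing(stream), band_hz = band_hz)
  tibble(
    speed_m_s = fit$speed_m_s,
    cadence_spm = cad$cadence_spm,
    speed_r2 = fit$r2,
    trimmed_fraction = 1 - fit$n_kept / n_clean,
    quality_flag = if (fit$converged) "ok" else "trim_failed",
    source = "kinect"
  )
}

#' Per-trial gait metrics from a floor-vibration record
#'
#' Runs the full accelerometer pipeline: zero-phase Butterworth
#' preprocessing, inter-DAQ clock synchronization, SNR-max footstep
#' detection, interval-based cadence, energy-decay localization, and
#' constant-speed Kalman tracking. Speed is fitted only over steps
#' localized inside the monitored zone (the hallway center), where walking
#' is steady-state; steps in the acceleration/deceleration zones are
#' excluded.
#'
#' @param record A raw [vibration_record()].
#' @param config A [trial_config()] describing the hallway.
#' @param k_sigma,min_dist_s Passed to [detect_steps()].
#' @param decay_alpha Passed to [localize_steps()] (`NULL` = fit per trial).
#' @return One-row tibble: `speed_m_s`, `cadence_spm`, `n_steps_detected`,
#'   `daq_lag_s`, `quality_flag` (`ok` / `too_few_steps`), `source`. The
#'   localized step series is attached as `attr(., "steps")`.
#' @export
floor_gait_metrics <- function(record, config = trial_config(),
                               k_sigma = 9, min_dist_s = 0.3,
                               decay_alpha = NULL) {
  pre <- preprocess_vibration(record)
  lag_s <- NA_real_
  if (!is.null(pre$sync_pair)) {
    sync <- synchronize_record(pre)
    pre <- sync$record
    lag_s <- sync$lag_s
  }
  steps <- detect_steps(snr_max(pre), k_sigma = k_sigma,
                        min_dist_s = min_dist_s)
  if (nrow(steps) < 4) {
    return(tibble(speed_m_s = NA_real_, cadence_spm = NA_real_,
                  n_steps_detected = nrow(steps), daq_lag_s = lag_s,
                  quality_flag = "too_few_steps", source = "accelerometer"))
  }
  cad <- cadence_from_steps(steps)
  steps <- localize_steps(pre, steps, decay_alpha = decay_alpha)
  zone <- c(config$accel_zone, config$hallway_length - config$accel_zone)
  in_zone <- !is.na(steps$position_m) &
    steps$position_m >= zone[1] & steps$position_m <= zone[2]
  speed <- NA_real_
  flag <- "ok"
  if (sum(in_zone) >= 4) {
    speed <- kalman_speed(steps[in_zone, ])$speed_m_s
  } else {
    flag <- "too_few_steps"
  }
  out <- tibble(speed_m_s = speed, cadence_spm = cad$cadence_spm,
                n_steps_detected = nrow(steps), daq_lag_s = lag_s,
                quality_flag = flag, source = "accelerometer")
  attr(out, "steps") <- steps
  out
}
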