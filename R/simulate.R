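#' Walker simulation parameters
#'
#' Kinematic and body-tracking parameters of the synthetic walker. Speed,
#' cadence and step length are linked by `speed = cadence / 60 * step_length`
#' during steady-state walking, so `step_length` is derived from the other
#' two. Defaults emulate a typical adult clinical cohort: 1.2 m/s at
#' 111 steps/min.
#'
#' @param speed Steady-state gait speed, m/s.
#' @param cadence Cadence, steps/min.
#' @param start_u Along-hallway position of the first heel strike, m.
#' @param joint_noise_sd Per-coordinate tracking noise SD, m (5 mm default).
#' @param dropout_prob Per-frame probability that the tracker drops the
#'   whole skeleton.
#' @param lead_dropout_frames Forced dropout run at the start and end of the
#'   stream (the tracker acquires/loses the subject at the hallway ends).
#' @param fps Camera frame rate, Hz.
#' @param time_jitter_sd Timestamp jitter SD, s.
#' @param tail_s Duration of the acceleration and deceleration tails, s.
#' @param torso,leg,shoulder Body segment lengths, m.
#' @return List of class `walker_params`.
#' @export
walker_params <- function(speed = 1.2, cadence = 111, start_u = 0.3,
                          joint_noise_sd = 0.005, dropout_prob = 0.02,
                          lead_dropout_frames = 5, fps = 30,
                          time_jitter_sd = 0.001, tail_s = 1,
                          torso = 0.6, leg = 0.9, shoulder = 0.38) {
  stopifnot(speed > 0, cadence > 0, dropout_prob >= 0, dropout_prob < 1,
            fps > 0, tail_s >= 0)
  structure(
    list(speed = speed, cadence = cadence,
         step_length = 60 * speed / cadence, start_u = start_u,
         joint_noise_sd = joint_noise_sd, dropout_prob = dropout_prob,
         lead_dropout_frames = lead_dropout_frames, fps = fps,
         time_jitter_sd = time_jitter_sd, tail_s = tail_s,
         torso = torso, leg = leg, shoulder = shoulder),
    class = "walker_params"
  )
}

#' Floor-vibration simulation parameters
#'
#' Each heel strike injects a Gaussian-windowed sinusoid (a damped
#' footstep transient, centered by default at 80 Hz — inside the 5-250 Hz
#' analysis passband) into every sensor, with amplitude proportional to
#' `exp(-decay_alpha * distance / 2)` so that energy decays as
#' `exp(-decay_alpha * distance)`. Channels of the second DAQ group are
#' delayed by `daq_lag_s` to emulate independent wireless clocks.
#'
#' @param amplitude Impulse peak amplitude at the source.
#' @param decay_alpha Energy decay constant, 1/m.
#' @param center_freq_hz Impulse center frequency, Hz (must sit inside the
#'   5-250 Hz passband).
#' @param impulse_sd_s Gaussian envelope SD of the impulse, s.
#' @param noise_sd Additive Gaussian sensor noise SD.
#' @param daq_lag_s Clock offset of the second DAQ group, s.
#' @param sample_rate Sampling rate, Hz (at least 2 kHz).
#' @return List of class `vibe_params`.
#' @export
vibe_params <- function(amplitude = 1, decay_alpha = 0.4, center_freq_hz = 80,
                        impulse_sd_s = 0.008, noise_sd = 0.02,
                        daq_lag_s = 0.1, sample_rate = 16384) {
  stopifnot(sample_rate >= 2000, amplitude > 0, decay_alpha >= 0)
  if (center_freq_hz <= 5 || center_freq_hz >= 250) {
    abort("center_freq_hz must lie inside the 5-250 Hz passband")
  }
  structure(
    list(amplitude = amplitude, decay_alpha = decay_alpha,
         center_freq_hz = center_freq_hz, impulse_sd_s = impulse_sd_s,
         noise_sd = noise_sd, daq_lag_s = daq_lag_s,
         sample_rate = sample_rate),
    class = "vibe_params"
  )
}

#' Simulate one walking trial with ground truth
#'
#' Generates a paired skeleton stream and floor-vibration record for one
#' hallway walk. The walker accelerates over `tail_s` seconds, cruises at
#' constant speed, and decelerates symmetrically; the pelvis carries small
#' vertical (step-frequency) and lateral (stride-frequency) gait-cycle
#' oscillations and the ankles swing about the pelvis at the stride
#' frequency with alternating phase. Heel strikes occur every
#' `step_length` meters; each injects a damped impulse into all sensors
#' with exponentially decaying energy. Frame dropouts (random plus forced
#' leading/trailing runs) and joint noise emulate tracker behaviour.
#'
#' @param walker A [walker_params()].
#' @param vibe A [vibe_params()].
#' @param config A [trial_config()].
#' @param layout Sensor layout (see [default_sensor_layout()]).
#' @param walk_line_v Across-hallway coordinate of the walking line, m.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param modalities Which modalities to generate (subset of
#'   `c("joints", "vibration")`).
#' @return List with `joints` ([joint_stream()] or `NULL`), `vibration`
#'   ([vibration_record()] or `NULL`) and `truth` (list: `speed`, `cadence`,
#'   `step_length`, `step_times`, `step_positions`, `foot`, `daq_lag_s`,
#'   `total_time_s`, `dropout_frames`).
#' @export
simulate_trial <- function(walker = walker_params(), vibe = vibe_params(),
                           config = trial_config(),
                           layout = default_sensor_layout(config$hallway_length),
                           walk_line_v = 1.75, seed = NULL,
                           modalities = c("joints", "vibration")) {
  if (!is.null(seed)) set.seed(seed)
  modalities <- match.arg(modalities, several.ok = TRUE)
  L <- config$hallway_length
  cruise_dist <- L - walker$speed * walker$tail_s
  if (cruise_dist <= 0) abort("walk does not fit in the hallway at this speed/tail")
  a <- if (walker$tail_s > 0) walker$speed / walker$tail_s else Inf
  d_tail <- walker$speed * walker$tail_s / 2
  t_cruise <- cruise_dist / walker$speed
  T_total <- 2 * walker$tail_s + t_cruise

  if (walker$tail_s == 0) {
    u_of_t <- function(t) walker$speed * t
    t_of_u <- function(u) u / walker$speed
  } else {
    u_of_t <- function(t) {
      ifelse(t <= walker$tail_s, 0.5 * a * pmax(t, 0)^2,
        ifelse(t <= walker$tail_s + t_cruise,
               d_tail + walker$speed * (t - walker$tail_s),
               L - 0.5 * a * pmax(T_total - t, 0)^2))
    }
    t_of_u <- function(u) {
      ifelse(u <= d_tail, sqrt(2 * u / a),
        ifelse(u <= d_tail + cruise_dist,
               walker$tail_s + (u - d_tail) / walker$speed,
               T_total - sqrt(2 * pmax(L - u, 0) / a)))
    }
  }

  # heel strikes at the cadence interval; positions follow the motion
  # profile, so cruise-phase spacing equals step_length exactly while the
  # tails show the shorter steps of an accelerating walker
  t_first <- t_of_u(walker$start_u)
  step_t <- seq(t_first, T_total, by = 60 / walker$cadence)
  step_u <- u_of_t(step_t)
  keep <- step_u > 0 & step_u < L
  step_t <- step_t[keep]
  step_u <- step_u[keep]
  foot <- rep_len(c("left", "right"), length(step_u))

  truth <- list(speed = walker$speed, cadence = walker$cadence,
                step_length = walker$step_length,
                step_times = step_t, step_positions = step_u, foot = foot,
                daq_lag_s = vibe$daq_lag_s, total_time_s = T_total,
                dropout_frames = integer(0))

  joints <- NULL
  if ("joints" %in% modalities) {
    sim <- simulate_joints(walker, walk_line_v, u_of_t, T_total)
    joints <- sim$stream
    truth$dropout_frames <- sim$dropout_frames
  }
  vibration <- NULL
  if ("vibration" %in% modalities) {
    vibration <- simulate_vibration(vibe, layout, walk_line_v,
                                    step_t, step_u, T_total)
  }
  list(joints = joints, vibration = vibration, truth = truth)
}

simulate_joints <- function(walker, walk_line_v, u_of_t, T_total) {
  f_step <- walker$cadence / 60     # steps per second
  f_stride <- f_step / 2            # per-foot periodicity
  tt <- seq(0, T_total, by = 1 / walker$fps)
  if (walker$time_jitter_sd > 0) {
    jit <- rnorm(length(tt), 0, walker$time_jitter_sd)
    tt <- tt + pmin(pmax(jit, -0.45 / walker$fps), 0.45 / walker$fps)
    tt <- tt - tt[1]
  }
  n <- length(tt)
  u <- u_of_t(tt)
  ph <- 2 * pi * f_stride * tt
  pelvis <- cbind(u,
                  walk_line_v + 0.02 * sin(ph),
                  0.95 + 0.015 * sin(2 * pi * f_step * tt))
  off <- function(du, dv, dz) pelvis + cbind(rep(du, n), rep(dv, n), rep(dz, n))
  ankle <- function(side) {
    s <- if (side == "left") 0 else pi
    pelvis + cbind(0.18 * sin(ph + s),
                   rep(if (side == "left") 0.12 else -0.12, n),
                   -0.85 + 0.05 * cos(ph + s))
  }
  ank_l <- ankle("left"); ank_r <- ankle("right")
  hip_l <- off(0, 0.10, -0.05); hip_r <- off(0, -0.10, -0.05)
  joints <- list(
    pelvis = pelvis,
    spine_navel = off(0, 0, walker$torso * 0.33),
    spine_chest = off(0, 0, walker$torso * 0.66),
    neck = off(0, 0, walker$torso),
    clavicle_left = off(0, 0.05, walker$torso - 0.02),
    shoulder_left = off(0, walker$shoulder / 2, walker$torso),
    elbow_left = off(0, walker$shoulder / 2 + 0.02, walker$torso - 0.3),
    wrist_left = off(0.05, walker$shoulder / 2 + 0.02, walker$torso - 0.55),
    hand_left = off(0.08, walker$shoulder / 2 + 0.02, walker$torso - 0.6),
    handtip_left = off(0.12, walker$shoulder / 2 + 0.02, walker$torso - 0.63),
    thumb_left = off(0.09, walker$shoulder / 2, walker$torso - 0.58),
    clavicle_right = off(0, -0.05, walker$torso - 0.02),
    shoulder_right = off(0, -walker$shoulder / 2, walker$torso),
    elbow_right = off(0, -walker$shoulder / 2 - 0.02, walker$torso - 0.3),
    wrist_right = off(0.05, -walker$shoulder / 2 - 0.02, walker$torso - 0.55),
    hand_right = off(0.08, -walker$shoulder / 2 - 0.02, walker$torso - 0.6),
    handtip_right = off(0.12, -walker$shoulder / 2 - 0.02, walker$torso - 0.63),
    thumb_right = off(0.09, -walker$shoulder / 2, walker$torso - 0.58),
    hip_left = hip_l, knee_left = hip_l + (ank_l - hip_l) / 2, ankle_left = ank_l,
    foot_left = ank_l + cbind(rep(0.1, n), 0, rep(-0.05, n)),
    hip_right = hip_r, knee_right = hip_r + (ank_r - hip_r) / 2, ankle_right = ank_r,
    foot_right = ank_r + cbind(rep(0.1, n), 0, rep(-0.05, n)),
    head = off(0, 0, walker$torso + 0.18),
    nose = off(0.08, 0, walker$torso + 0.18),
    eye_left = off(0.06, 0.03, walker$torso + 0.2),
    ear_left = off(0, 0.07, walker$torso + 0.18),
    eye_right = off(0.06, -0.03, walker$torso + 0.2),
    ear_right = off(0, -0.07, walker$torso + 0.18)
  )
  stopifnot(identical(names(joints), kinect_joints))
  mat <- do.call(cbind, joints)
  if (walker$joint_noise_sd > 0) {
    mat <- mat + rnorm(length(mat), 0, walker$joint_noise_sd)
  }
  drop <- runif(n) < walker$dropout_prob
  k <- walker$lead_dropout_frames
  if (k > 0) {
    drop[seq_len(min(k, n))] <- TRUE
    drop[seq.int(max(1, n - k + 1), n)] <- TRUE
  }
  mat[drop, ] <- NA_real_
  df <- as.data.frame(mat)
  names(df) <- unlist(lapply(kinect_joints, joint_cols))
  stream <- joint_stream(dplyr::bind_cols(tibble(time_s = tt), df))
  list(stream = stream, dropout_frames = which(drop))
}

simulate_vibration <- function(vibe, layout, walk_line_v, step_t, step_u,
                               T_total) {
  fs <- vibe$sample_rate
  n <- round((T_total + 0.3) * fs)
  sd_t <- vibe$impulse_sd_s
  half <- ceiling(4 * sd_t * fs)
  clean <- matrix(0, n, nrow(layout))
  for (k in seq_along(step_t)) {
    i0 <- round(step_t[k] * fs)
    idx <- max(1L, i0 - half):min(n, i0 + half)
    tau <- (idx - i0) / fs
    g <- exp(-tau^2 / (2 * sd_t^2)) * sin(2 * pi * vibe$center_freq_hz * tau)
    d <- sqrt((step_u[k] - layout$u_m)^2 + (walk_line_v - layout$v_m)^2)
    amp <- vibe$amplitude * exp(-vibe$decay_alpha * d / 2)
    for (s in seq_len(nrow(layout))) {
      clean[idx, s] <- clean[idx, s] + amp[s] * g
    }
  }
  # co-located duplicate: sensor 4 carries sensor 5's position already
  # (identical u/v in the layout), so its clean signal matches sensor 5's.
  lag_n <- round(vibe$daq_lag_s * fs)
  second <- unique(layout$daq_group)[2]
  chans <- lapply(seq_len(nrow(layout)), function(s) {
    x <- clean[, s]
    if (layout$daq_group[s] == second && lag_n != 0) {
      x <- shift_series(x, -lag_n)  # delayed clock
    }
    x + rnorm(n, 0, vibe$noise_sd)
  })
  names(chans) <- paste0("ch", seq_along(chans))
  vibration_record(as_tibble(chans), sample_rate = fs, layout = layout,
                   sync_pair = c(4L, 5L), walk_line_v = walk_line_v)
}

#' Write a simulated trial to disk
#'
#' Writes the joint stream CSV, the vibration CSV + JSON sidecar, and the
#' ground truth JSON into a directory.
#'
#' @param trial Result of [simulate_trial()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!is.null(trial$joints)) {
    write_joint_stream(trial$joints, file.path(dir, "joints.csv"))
  }
  if (!is.null(trial$vibration)) {
    write_vibration(trial$vibration, file.path(dir, "vibration.csv"),
                    file.path(dir, "vibration.json"))
  }
  jsonlite::write_json(trial$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
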