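# Fixture builders shared across the suite. Everything is generated in code;
# no data files are read.

# minimal stream carrying only the named joints
make_stream <- function(time_s, ...) {
  joints <- list(...)
  df <- tibble::tibble(time_s = time_s)
  for (j in names(joints)) {
    m <- joints[[j]]
    df[[paste0(j, "_x")]] <- m[, 1]
    df[[paste0(j, "_y")]] <- m[, 2]
    df[[paste0(j, "_z")]] <- m[, 3]
  }
  walksense::joint_stream(df)
}

# uniformly random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# apply a rigid transform (rotation + translation) to every joint column
rigid_transform_stream <- function(stream, rot = random_rotation(),
                                   shift = rnorm(3)) {
  df <- tibble::as_tibble(as.data.frame(stream))
  base <- unique(sub("_[xyz]$", "", setdiff(names(df), "time_s")))
  for (j in base) {
    cols <- paste0(j, "_", c("x", "y", "z"))
    xyz <- as.matrix(df[cols]) %*% t(rot)
    xyz <- sweep(xyz, 2, shift, "+")
    df[cols] <- xyz
  }
  walksense::joint_stream(df)
}

# distance series built directly (bypassing pelvis extraction)
make_distance_series <- function(time_s, distance_m,
                                 valid = !is.na(distance_m)) {
  out <- tibble::tibble(time_s = time_s, distance_m = distance_m,
                        valid = valid)
  class(out) <- c("distance_series", class(out))
  out
}

# hand-built SNR series with the attributes detect_steps() expects
make_snr_series <- function(window_time_s, snr_max_values, window_s = 0.02) {
  out <- tibble::tibble(window_time_s = window_time_s,
                        snr_max = snr_max_values)
  attr(out, "window_s") <- window_s
  class(out) <- c("snr_series", class(out))
  out
}

# step series built directly from times (and optional positions)
make_step_series <- function(step_time_s, position_m = NULL) {
  out <- tibble::tibble(step_time_s = step_time_s,
                        snr = rep(1, length(step_time_s)))
  if (!is.null(position_m)) out$position_m <- position_m
  attr(out, "window_s") <- 0.02
  class(out) <- c("step_series", class(out))
  out
}

# small vibration record with a custom channel count (no sync pair)
make_record <- function(channels, sample_rate, u_m = NULL, v_m = NULL,
                        walk_line_v = 0) {
  nch <- ncol(as.data.frame(channels))
  layout <- tibble::tibble(
    sensor = seq_len(nch),
    u_m = u_m %||% seq(0, by = 5, length.out = nch),
    v_m = v_m %||% rep(0, nch),
    daq_group = rep("left", nch)
  )
  walksense::vibration_record(channels, sample_rate, layout,
                              sync_pair = NULL, walk_line_v = walk_line_v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rigid synthetic skeleton with exact segment lengths, n frames
make_rigid_skeleton <- function(n = 20, torso = 0.6, leg = 0.9,
                                shoulder = 0.4, scale = 1) {
  t <- seq(0, by = 1 / 30, length.out = n)
  z <- function(dz) cbind(rep(0, n), rep(0, n), rep(dz, n))
  pelvis <- cbind(t, rep(0, n), rep(1, n))  # translating: lengths unaffected
  make_stream(
    t,
    pelvis = pelvis * scale,
    neck = (pelvis + z(torso)) * scale,
    shoulder_left = (pelvis + cbind(rep(0, n), rep(shoulder / 2, n), rep(torso, n))) * scale,
    shoulder_right = (pelvis + cbind(rep(0, n), rep(-shoulder / 2, n), rep(torso, n))) * scale,
    hip_left = (pelvis + cbind(rep(0, n), rep(0.1, n), rep(0, n))) * scale,
    knee_left = (pelvis + cbind(rep(0, n), rep(0.1, n), rep(-leg / 2, n))) * scale,
    ankle_left = (pelvis + cbind(rep(0, n), rep(0.1, n), rep(-leg, n))) * scale,
    hip_right = (pelvis + cbind(rep(0, n), rep(-0.1, n), rep(0, n))) * scale,
    knee_right = (pelvis + cbind(rep(0, n), rep(-0.1, n), rep(-leg / 2, n))) * scale,
    ankle_right = (pelvis + cbind(rep(0, n), rep(-0.1, n), rep(-leg, n))) * scale
  )
}
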