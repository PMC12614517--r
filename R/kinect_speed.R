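#' Pelvis displacement series
#'
#' Computes the 3-D Euclidean distance of the pelvis from its first tracked
#' position in every frame. Because the distance is a norm of coordinate
#' differences, the result — and every quantity derived from it — is
#' invariant to the camera's placement and orientation (any rigid transform
#' of the joint coordinates).
#'
#' @param stream A [joint_stream()].
#' @return A tibble of class `distance_series` with columns `time_s`,
#'   `distance_m` (NA on dropout frames) and `valid`.
#' @export
pelvis_distance <- function(stream) {
  p <- joint_xyz(stream, "pelvis")
  valid <- !is.na(p[, 1])
  if (sum(valid) < 2) {
    abort("need at least 2 frames with a tracked pelvis")
  }
  p0 <- p[which(valid)[1], ]
  d <- sqrt((p[, 1] - p0[1])^2 + (p[, 2] - p0[2])^2 + (p[, 3] - p0[3])^2)
  out <- tibble(time_s = stream$time_s, distance_m = d, valid = valid)
  class(out) <- c("distance_series", class(out))
  out
}

#' Clean a displacement series of tracking dropouts
#'
#' Leading and trailing dropout runs are removed. Interior dropout runs of at
#' most `max_gap` samples are linearly interpolated from the adjacent valid
#' samples; longer interior runs split the series, in which case the longest
#' contiguous clean segment is kept and the result is flagged
#' (`attr(., "trimmed_to_segment")`).
#'
#' @param series A `distance_series` from [pelvis_distance()].
#' @param max_gap Longest interior dropout run (samples) to interpolate.
#' @param min_samples Minimum usable segment length; shorter is an error.
#' @return A `distance_series` with all samples valid. Attributes
#'   `trimmed_to_segment` (logical) and `dropped_fraction` record what was
#'   discarded.
#' @export
clean_distance <- function(series, max_gap = 2, min_samples = 2) {
  n0 <- nrow(series)
  valid <- series$valid & !is.na(series$distance_m)
  if (!any(valid)) abort("no valid samples in series")
  # trim leading/trailing dropout runs
  lo <- which(valid)[1]
  hi <- max(which(valid))
  series <- series[lo:hi, ]
  valid <- valid[lo:hi]

  # mark interior dropout runs longer than max_gap; they split the series
  r <- rle(valid)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  in_long_gap <- rep(FALSE, nrow(series))
  for (g in which(!r$values & r$lengths > max_gap)) {
    in_long_gap[run_start[g]:run_end[g]] <- TRUE
  }
  seg <- rle(!in_long_gap)
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths + 1
  usable <- which(seg$values)
  trimmed <- length(usable) > 1
  keep <- usable[which.max(seg$lengths[usable])]
  series <- series[seg_start[keep]:seg_end[keep], ]
  valid <- series$valid & !is.na(series$distance_m)

  if (sum(valid) < min_samples) {
    abort("no clean segment of the minimum length")
  }
  # interpolate remaining short interior gaps
  if (any(!valid)) {
    filled <- approx(series$time_s[valid], series$distance_m[valid],
                     xout = series$time_s, method = "linear")$y
    series$distance_m[!valid] <- filled[!valid]
    series$valid <- TRUE
  }
  attr(series, "trimmed_to_segment") <- trimmed
  attr(series, "dropped_fraction") <- 1 - nrow(series) / n0
  series
}

#' Gait speed from a linear fit with iterative end-trimming
#'
#' Ordinary least squares of pelvis displacement on time: the slope is the
#' gait speed. Walks include acceleration and deceleration tails outside the
#' monitored zone, so the fit is trimmed iteratively — one sample removed
#' from each end per iteration — until the coefficient of determination
#' exceeds `r2_threshold` or the series shrinks to `min_points`, in which
#' case `converged = FALSE` flags a failed trial (an automated stand-in for
#' manual review).
#'
#' @param series A cleaned `distance_series` (see [clean_distance()]).
#' @param r2_threshold Minimum acceptable R-squared (default 0.98).
#' @param min_points Smallest series length the trimmer may reach
#'   (default 30 samples, about one second at 30 fps).
#' @return An object of class `gait_speed_fit`: list with `speed_m_s`,
#'   `intercept_m`, `r2`, `n_kept`, `trim_left`, `trim_right`, `converged`,
#'   and the kept `data`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_gait_speed <- function(series, r2_threshold = 0.98, min_points = 30) {
  t <- series$time_s
  d <- series$distance_m
  if (anyNA(d)) abort("series must be cleaned before fitting (see clean_distance)")
  n <- length(t)
  if (n < min_points) abort(sprintf("series has %d points; need at least %d", n, min_points))

  lo <- 1L; hi <- n
  fit <- ols_line(t[lo:hi], d[lo:hi])
  while (fit$r2 <= r2_threshold && (hi - lo + 1) - 2 >= min_points) {
    lo <- lo + 1L
    hi <- hi - 1L
    fit <- ols_line(t[lo:hi], d[lo:hi])
  }
  structure(
    list(speed_m_s = fit$slope, intercept_m = fit$intercept, r2 = fit$r2,
         n_kept = hi - lo + 1L, trim_left = lo - 1L, trim_right = n - hi,
         converged = fit$r2 > r2_threshold,
         r2_threshold = r2_threshold,
         data = tibble(time_s = t, distance_m = d,
                       kept = seq_len(n) >= lo & seq_len(n) <= hi)),
    class = "gait_speed_fit"
  )
}

# simple-regression slope/intercept/R2; R2 = squared Pearson correlation,
# defined as 0 when either variable is constant
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  syy <- sum((y - my)^2)
  slope <- sxy / sxx
  r2 <- if (sxx <= 0 || syy <= 0) 0 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' @export
print.gait_speed_fit <- function(x, ...) {
  cat(sprintf(
    "<gait_speed_fit> speed %.3f m/s, R^2 %.4f, kept %d frames (trim %d+%d)%s\n",
    x$speed_m_s, x$r2, x$n_kept, x$trim_left, x$trim_right,
    if (x$converged) "" else " [trim failed]"))
  invisible(x)
}
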