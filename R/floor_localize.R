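#' Localize detected footsteps along the hallway
#'
#' Energy-based localization. For each detected step, the signal energy at
#' each sensor is integrated over a short window around the step time and
#' normalized by that sensor's noise-floor energy (median window energy over
#' the whole record), which cancels per-channel gain. Footstep energy is
#' modeled as decaying exponentially with distance from the impact:
#' `log E_s = log E0 - alpha * d_s(u)`, with `d_s(u)` the distance from a
#' candidate position `u` on the walking line to sensor `s`. The position is
#' the profile least-squares solution on the hallway axis; the across-hallway
#' offset of the walking line is absorbed into the effective distance.
#'
#' Because hallway floors are not homogeneous media, the decay constant is
#' uncertain: when `decay_alpha` is `NULL` it is fitted per trial — each
#' step is first fitted with a free slope, the per-trial alpha is the median
#' of the per-step estimates, and positions are then re-fitted at that
#' common alpha.
#'
#' @param record A preprocessed, synchronized [vibration_record()].
#' @param steps A `step_series` from [detect_steps()].
#' @param decay_alpha Energy decay constant (1/m), or `NULL` to fit per trial.
#' @param window_s Half-width of the per-step energy window, seconds.
#' @param grid_res_m Resolution of the position search grid, meters.
#' @param u_range Search interval for positions, m; defaults to the sensor
#'   span extended by 2 m each way.
#' @return `steps` with a `position_m` column; the fitted alpha in
#'   `attr(., "decay_alpha")`.
#' @export
localize_steps <- function(record, steps, decay_alpha = NULL,
                           window_s = 0.05, grid_res_m = 0.02,
                           u_range = NULL) {
  fs <- record$sample_rate
  n <- nrow(record$data)
  E <- step_energies(record, steps$step_time_s, window_s)
  # noise-floor normalization per sensor (cancels per-channel gain)
  nw <- max(1L, round(2 * window_s * fs))
  n_win <- n %/% nw
  norm <- vapply(record$data, function(x) {
    m <- median(colSums(matrix(x[seq_len(n_win * nw)]^2, nrow = nw)))
    if (m > 0) m else 1
  }, numeric(1))
  E <- sweep(E, 2, norm, "/")

  u_s <- record$layout$u_m
  v_s <- record$layout$v_m
  vw <- record$walk_line_v
  if (is.null(u_range)) u_range <- range(u_s) + c(-2, 2)
  grid <- seq(u_range[1], u_range[2], by = grid_res_m)
  dists <- sqrt(outer(grid, u_s, "-")^2 +
                  matrix((vw - v_s)^2, length(grid), length(u_s), byrow = TRUE))

  fit_free <- function(logE) {
    # minimize RSS of logE ~ d(u) over the grid; slope must be negative
    best <- list(rss = Inf, u = NA_real_, alpha = NA_real_)
    for (g in seq_along(grid)) {
      f <- ols_line(dists[g, ], logE)
      if (f$slope < 0) {
        rss <- sum((logE - f$intercept - f$slope * dists[g, ])^2)
        if (rss < best$rss) best <- list(rss = rss, u = grid[g], alpha = -f$slope)
      }
    }
    best
  }
  fit_fixed <- function(logE, alpha) {
    # at fixed alpha the intercept profile is the mean; RSS = variance term
    rss <- vapply(seq_along(grid),
                  function(g) sum((logE + alpha * dists[g, ] -
                                     mean(logE + alpha * dists[g, ]))^2),
                  numeric(1))
    g <- which.min(rss)
    obj <- function(u) {
      d <- sqrt((u - u_s)^2 + (vw - v_s)^2)
      r <- logE + alpha * d
      sum((r - mean(r))^2)
    }
    stats::optimize(obj, lower = max(u_range[1], grid[g] - grid_res_m),
                    upper = min(u_range[2], grid[g] + grid_res_m))$minimum
  }

  logE <- log(E)
  usable <- apply(is.finite(logE), 1, all)
  if (!any(usable)) abort("all step energies below the noise floor")
  if (is.null(decay_alpha)) {
    alphas <- vapply(which(usable), function(i) fit_free(logE[i, ])$alpha,
                     numeric(1))
    decay_alpha <- median(alphas[is.finite(alphas) & alphas > 0])
    if (!is.finite(decay_alpha)) {
      abort("could not fit a positive decay constant on any step")
    }
  }
  pos <- rep(NA_real_, nrow(steps))
  pos[usable] <- vapply(which(usable),
                        function(i) fit_fixed(logE[i, ], decay_alpha),
                        numeric(1))
  steps$position_m <- pos
  attr(steps, "decay_alpha") <- decay_alpha
  steps
}

# steps x sensors energy matrix over +/- window_s around each step time
step_energies <- function(record, step_times, window_s) {
  fs <- record$sample_rate
  n <- nrow(record$data)
  t(vapply(step_times, function(t0) {
    i0 <- max(1L, round((t0 - window_s) * fs))
    i1 <- min(n, round((t0 + window_s) * fs))
    vapply(record$data, function(x) sum(x[i0:i1]^2), numeric(1))
  }, numeric(ncol(record$data))))
}

#' Gait speed from localized steps via constant-speed Kalman tracking
#'
#' Filters the step positions with a constant-speed kinematic model
#' (state: position and speed) and smooths the result backwards
#' (Rauch-Tung-Striebel). Measurement variance is estimated from the
#' residuals of a robust straight-line pre-fit, and observations whose
#' normalized innovation exceeds `gate_nis` are skipped — this is what
#' corrects step locations mistakenly localized far from the track. The
#' reported gait speed is the slope of the smoothed positions over the step
#' times (equal to the terminal smoothed speed for a constant-speed walk).
#'
#' @param steps A `step_series` with `position_m` (see [localize_steps()]),
#'   at least 4 localized steps, strictly increasing times.
#' @param q_speed Process-noise spectral density on speed (m^2/s^3); small,
#'   since walking speed is quasi-constant.
#' @param r_meas Measurement variance (m^2); `NULL` estimates it from a
#'   robust pre-fit.
#' @param gate_nis Normalized-innovation-squared gate for rejecting
#'   observations.
#' @return Object of class `step_track`: `speed_m_s`, `terminal_speed_m_s`,
#'   `r_meas`, `n_gated`, and the `track` tibble (`time_s`, `observed_m`,
#'   `smoothed_m`, `used`). Supports [tidy()], [glance()], `autoplot()`.
#' @export
kalman_speed <- function(steps, q_speed = 0.01, r_meas = NULL, gate_nis = 9) {
  ok <- !is.na(steps$position_m)
  t <- steps$step_time_s[ok]
  z <- steps$position_m[ok]
  if (length(t) < 4) abort("need at least 4 localized steps")
  if (any(diff(t) <= 0)) abort("step times must be strictly increasing")

  pre <- tryCatch(MASS::rlm(z ~ t, maxit = 100),
                  error = function(e) lm(z ~ t), warning = function(w) lm(z ~ t))
  fixed_r <- !is.null(r_meas)
  if (!fixed_r) {
    r_meas <- max(mad(residuals(pre))^2, 1e-12)
  }
  v0 <- unname(coef(pre)[2])
  n <- length(t)

  run <- function(r_meas) {
    x <- c(z[1], v0)
    P <- diag(c(r_meas, max(0.25 * v0^2, 0.25)))
    xf <- matrix(0, n, 2); Pf <- array(0, c(n, 2, 2))
    xp <- matrix(0, n, 2); Pp <- array(0, c(n, 2, 2))
    xf[1, ] <- x; Pf[1, , ] <- P; xp[1, ] <- x; Pp[1, , ] <- P
    used <- rep(TRUE, n)
    for (i in 2:n) {
      dt <- t[i] - t[i - 1]
      F_ <- matrix(c(1, 0, dt, 1), 2, 2)
      Q <- q_speed * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
      x <- F_ %*% x
      P <- F_ %*% P %*% t(F_) + Q
      xp[i, ] <- x; Pp[i, , ] <- P
      innov <- z[i] - x[1]
      S <- P[1, 1] + r_meas
      if (innov^2 / S <= gate_nis) {
        K <- P[, 1] / S
        x <- x + K * innov
        P <- P - outer(K, P[1, ])
      } else {
        used[i] <- FALSE
      }
      xf[i, ] <- x; Pf[i, , ] <- P
    }
    # Rauch-Tung-Striebel smoother
    xs <- xf; Ps <- Pf
    for (i in (n - 1):1) {
      dt <- t[i + 1] - t[i]
      F_ <- matrix(c(1, 0, dt, 1), 2, 2)
      G <- Pf[i, , ] %*% t(F_) %*% solve(Pp[i + 1, , ])
      xs[i, ] <- xf[i, ] + G %*% (xs[i + 1, ] - xp[i + 1, ])
      Ps[i, , ] <- Pf[i, , ] + G %*% (Ps[i + 1, , ] - Pp[i + 1, , ]) %*% t(G)
    }
    list(xs = xs, used = used, r_meas = r_meas)
  }

  # a too-small noise estimate from the pre-fit would gate legitimate
  # observations wholesale; inflate it until most observations are used
  res <- run(r_meas)
  if (!fixed_r) {
    tries <- 0
    while (sum(!res$used) > 0.3 * n && tries < 5) {
      r_meas <- r_meas * 4
      res <- run(r_meas)
      tries <- tries + 1
    }
  }
  xs <- res$xs
  slope <- ols_line(t, xs[, 1])$slope
  structure(
    list(speed_m_s = slope, terminal_speed_m_s = xs[n, 2],
         r_meas = res$r_meas, n_gated = sum(!res$used),
         track = tibble(time_s = t, observed_m = z, smoothed_m = xs[, 1],
                        speed_m_s = xs[, 2], used = res$used)),
    class = "step_track"
  )
}

#' @export
print.step_track <- function(x, ...) {
  cat(sprintf("<step_track> speed %.3f m/s over %d steps (%d gated)\n",
              x$speed_m_s, nrow(x$track), x$n_gated))
  invisible(x)
}
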