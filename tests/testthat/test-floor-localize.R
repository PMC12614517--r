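# record with one exact exponential-decay impulse per requested position
impulse_record <- function(positions, alpha = 0.4, fs = 2048, dur = NULL,
                           u_s = c(2, 7, 12, 2, 7, 12),
                           v_s = c(0, 0, 0, 3.5, 3.5, 3.5),
                           walk_line_v = 1.75, noise_sd = 0,
                           gains = rep(1, length(u_s))) {
  times <- seq(1, by = 0.6, length.out = length(positions))
  dur <- dur %||% (max(times) + 1)
  n <- round(dur * fs)
  ch <- matrix(0, n, length(u_s))
  for (k in seq_along(positions)) {
    i0 <- round(times[k] * fs)
    idx <- i0 + (-60:60)
    tau <- (-60:60) / fs
    g <- exp(-tau^2 / (2 * 0.008^2)) * sin(2 * pi * 80 * tau)
    d <- sqrt((positions[k] - u_s)^2 + (walk_line_v - v_s)^2)
    for (s in seq_along(u_s)) {
      ch[idx, s] <- ch[idx, s] + gains[s] * exp(-alpha * d[s] / 2) * g
    }
  }
  if (noise_sd > 0) ch <- ch + rnorm(length(ch), sd = noise_sd)
  rec <- make_record(as.data.frame(ch), fs, u_m = u_s, v_m = v_s,
                     walk_line_v = walk_line_v)
  list(record = rec, steps = make_step_series(times))
}

test_that("noiseless exponential-decay impulses are localized accurately", {
  f <- impulse_record(c(4, 6.5, 9), alpha = 0.4)
  st <- localize_steps(f$record, f$steps, decay_alpha = 0.4)
  expect_lt(max(abs(st$position_m - c(4, 6.5, 9))), 0.1)
})

test_that("the trial-level decay constant is recovered when not supplied", {
  f <- impulse_record(seq(3, 11, by = 1), alpha = 0.6)
  st <- localize_steps(f$record, f$steps)
  expect_equal(attr(st, "decay_alpha"), 0.6, tolerance = 0.05)
  expect_lt(max(abs(st$position_m - seq(3, 11, by = 1))), 0.15)
})

test_that("an impulse equidistant from sensor columns lands at the midpoint", {
  f <- impulse_record(4.5, alpha = 0.5)  # midway between u = 2 and u = 7
  st <- localize_steps(f$record, f$steps, decay_alpha = 0.5)
  expect_equal(st$position_m, 4.5, tolerance = 0.05)
})

test_that("localization is invariant to a global gain", {
  set.seed(81)
  f <- impulse_record(c(4, 7, 10), alpha = 0.4, noise_sd = 1e-4)
  a <- localize_steps(f$record, f$steps, decay_alpha = 0.4)
  f$record$data <- f$record$data * 12.5
  b <- localize_steps(f$record, f$steps, decay_alpha = 0.4)
  expect_equal(b$position_m, a$position_m, tolerance = 1e-9)
})

test_that("localization is invariant to per-channel gains (noise-floor normalization)", {
  set.seed(82)
  gains <- c(1, 2, 0.5, 3, 0.2, 1.7)
  f1 <- impulse_record(c(4, 7, 10), alpha = 0.4, noise_sd = 1e-4)
  f2 <- impulse_record(c(4, 7, 10), alpha = 0.4, noise_sd = 0)
  # apply gains to both signal and an identical noise realization
  set.seed(99); n1 <- matrix(rnorm(nrow(f2$record$data) * 6, sd = 1e-4), ncol = 6)
  d_ref <- as.data.frame(as.matrix(f2$record$data) + n1)
  d_gain <- as.data.frame(sweep(as.matrix(f2$record$data) + n1, 2, gains, "*"))
  ra <- make_record(d_ref, 2048, u_m = f2$record$layout$u_m,
                    v_m = f2$record$layout$v_m, walk_line_v = 1.75)
  rb <- make_record(d_gain, 2048, u_m = f2$record$layout$u_m,
                    v_m = f2$record$layout$v_m, walk_line_v = 1.75)
  a <- localize_steps(ra, f2$steps, decay_alpha = 0.4)
  b <- localize_steps(rb, f2$steps, decay_alpha = 0.4)
  expect_equal(b$position_m, a$position_m, tolerance = 1e-6)
})

test_that("noiseless linear tracks give the exact speed", {
  t <- seq(0, 6.5, by = 0.5)
  st <- make_step_series(t, position_m = 3 + 1.2 * t)
  ks <- kalman_speed(st)
  expect_equal(ks$speed_m_s, 1.2, tolerance = 1e-6)
  expect_equal(ks$n_gated, 0L)
})

test_that("a gross localization outlier is gated out", {
  t <- seq(0, 6.5, by = 0.5)
  pos <- 3 + 1.2 * t
  pos[7] <- pos[7] + 3  # mistakenly localized 3 m away
  ks <- kalman_speed(make_step_series(t, position_m = pos))
  # oracle: OLS on the inlier observations only
  oracle <- coef(lm(pos[-7] ~ t[-7]))[2]
  expect_lt(abs(ks$speed_m_s - 1.2) / 1.2, 0.10)
  expect_equal(ks$speed_m_s, unname(oracle), tolerance = 0.1)
  expect_gte(ks$n_gated, 1L)
})

test_that("kalman speed tolerates realistic localization noise", {
  set.seed(83)
  errs <- replicate(50, {
    t <- seq(0, 6.5, by = 0.5)
    pos <- 3 + 1.2 * t + rnorm(length(t), sd = 0.3)
    abs(kalman_speed(make_step_series(t, position_m = pos))$speed_m_s - 1.2) / 1.2
  })
  expect_lt(mean(errs < 0.15), 1.01)  # sanity: fractions
  expect_gt(mean(errs < 0.15), 0.95)
})

test_that("degenerate step tracks are rejected", {
  expect_error(kalman_speed(make_step_series(c(0, 0.5, 1), position_m = 1:3)),
               "at least 4")
  expect_error(kalman_speed(make_step_series(c(0, 0.5, 0.5, 1),
                                             position_m = 1:4)),
               "strictly increasing")
})
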