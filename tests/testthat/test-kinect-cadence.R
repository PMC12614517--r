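fs_sine <- function(f_left, f_right, dur = 30, fps = 30, amp = 0.05) {
  t <- seq(0, dur, by = 1 / fps)
  out <- tibble::tibble(time_s = t,
                        fs_left_m = 0.9 + amp * sin(2 * pi * f_left * t),
                        fs_right_m = 0.9 + amp * sin(2 * pi * f_right * t))
  class(out) <- c("foot_swing", class(out))
  out
}

test_that("cadence is 120 times the mean stride frequency", {
  c1 <- cadence_fft(fs_sine(0.90, 0.90))
  expect_equal(c1$cadence_spm, 108, tolerance = 1.2 / 108)
  c2 <- cadence_fft(fs_sine(0.90, 0.95))
  expect_equal(c2$cadence_spm, 111, tolerance = 1.2 / 111)
  expect_lte(c2$resolution_hz, 0.01)
})

test_that("cadence is invariant to foot-swing amplitude scaling", {
  a <- cadence_fft(fs_sine(0.8, 0.85, amp = 0.02))
  b <- cadence_fft(fs_sine(0.8, 0.85, amp = 0.02 * 37))
  expect_equal(a$cadence_spm, b$cadence_spm, tolerance = 1e-12)
})

test_that("short signals and empty bands are rejected", {
  expect_error(cadence_fft(fs_sine(0.9, 0.9, dur = 2)), "3 s")
  expect_error(cadence_fft(fs_sine(0.9, 0.9), band_hz = c(1.5, 0.5)),
               "increasing")
})

test_that("foot swing cancels translation and tracks relative motion", {
  n <- 60
  t <- seq(0, 2, length.out = n)
  pelvis <- cbind(1.2 * t, 0 * t, rep(1, n))
  s <- make_stream(t, pelvis = pelvis,
                   ankle_left = pelvis + cbind(rep(0, n), rep(0, n), rep(-0.9, n)),
                   ankle_right = pelvis + cbind(rep(0, n), rep(0, n),
                                                -0.9 + 0.1 * sin(2 * pi * t)))
  fsw <- foot_swing(s)
  expect_equal(fsw$fs_left_m, rep(0.9, n), tolerance = 1e-12)
  expect_true(all(fsw$fs_right_m >= 0.8 - 1e-9 & fsw$fs_right_m <= 1.0 + 1e-9))
})

test_that("foot swing is invariant under rigid transforms of all joints", {
  tr <- simulate_trial(seed = 21, modalities = "joints")
  set.seed(9)
  moved <- rigid_transform_stream(tr$joints)
  a <- foot_swing(tr$joints)
  b <- foot_swing(moved)
  expect_equal(b$fs_left_m, a$fs_left_m, tolerance = 1e-9)
  expect_equal(b$fs_right_m, a$fs_right_m, tolerance = 1e-9)
})

test_that("simulated walker cadence agrees with an autocorrelation oracle", {
  tr <- simulate_trial(walker_params(cadence = 120, speed = 1.2),
                       seed = 33, modalities = "joints")
  fsw <- foot_swing(tr$joints)
  est <- cadence_fft(fsw)
  expect_equal(est$cadence_spm, 120, tolerance = 1.2 / 120)

  # oracle: autocorrelation peak of the resampled left foot-swing signal
  ok <- !is.na(fsw$fs_left_m)
  dt <- median(diff(fsw$time_s[ok]))
  g <- seq(min(fsw$time_s[ok]), max(fsw$time_s[ok]), by = dt)
  x <- approx(fsw$time_s[ok], fsw$fs_left_m[ok], g)$y
  x <- x - mean(x)
  ac <- acf(x, lag.max = round(2.5 / dt), plot = FALSE)$acf[-1]
  lags <- seq_along(ac) * dt
  cand <- lags >= 1 / 1.5 & lags <= 1 / 0.5
  stride_period <- lags[cand][which.max(ac[cand])]
  cad_oracle <- 120 / stride_period
  expect_equal(est$cadence_spm, cad_oracle, tolerance = 0.03)
})

test_that("body dimensions recover exact rigid geometry and scale correctly", {
  s <- make_rigid_skeleton(n = 20, torso = 0.6, leg = 0.9, shoulder = 0.4)
  bd <- body_dimensions(s)
  expect_equal(bd$body_length_m, 1.5, tolerance = 1e-12)
  expect_equal(bd$body_area_m2, 0.6, tolerance = 1e-12)

  bd2 <- body_dimensions(make_rigid_skeleton(scale = 1.1))
  expect_equal(bd2$body_area_m2, 0.6 * 1.21, tolerance = 1e-12)
})

test_that("median body dimensions are robust to 5 mm joint noise", {
  set.seed(17)
  s <- make_rigid_skeleton(n = 100)
  df <- tibble::as_tibble(as.data.frame(s))
  pos <- setdiff(names(df), "time_s")
  df[pos] <- df[pos] + matrix(rnorm(nrow(df) * length(pos), sd = 0.005),
                              nrow(df))
  bd <- body_dimensions(joint_stream(df))
  expect_lt(abs(bd$body_area_m2 - 0.6) / 0.6, 0.01)
})

test_that("body-area normalization matches the closed form", {
  z <- normalize_body_area(c(1, 2, 2.5), c(TRUE, TRUE, FALSE))
  expect_equal(z[3], 1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(normalize_body_area(c(1, 2, 1.5), c(TRUE, TRUE, FALSE))[3], 0)
  expect_error(normalize_body_area(c(1, 1, 2), c(TRUE, TRUE, FALSE)),
               "zero variance")
})

test_that("a cohort simulated with a male shift recovers it in z-units", {
  set.seed(23)
  n <- 4000
  male <- rep(c(TRUE, FALSE), n / 2)
  area <- 0.62 + ifelse(male, 1.5 * 0.05, 0) + rnorm(n, 0, 0.05)
  z <- normalize_body_area(area, !male)
  expect_equal(mean(z[male]), 1.5, tolerance = 0.1)
})
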