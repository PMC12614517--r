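#' Cohort simulation parameters
#'
#' Generating parameters for a synthetic clinical cohort of walking trials.
#' Defaults emulate a preoperative adult cohort: regular-pace gait speed
#' around 1.2 m/s (SD 0.27) and cadence around 111 steps/min (SD 11), age
#' 66 +/- 13 years, 60% male, fast-pace trials scaling speed by 1.25 and
#' cadence by 1.14. Age effects are expressed per SD of age and are carved
#' out of the marginal SDs, so the stated marginal distributions hold
#' whatever the effect sizes.
#'
#' @param n Number of subjects.
#' @param speed_mean,speed_sd Marginal regular-pace speed distribution, m/s.
#' @param cadence_mean,cadence_sd Marginal cadence distribution, steps/min.
#' @param within_sd_speed,within_sd_cadence Trial-to-trial (test-retest)
#'   within-subject SDs.
#' @param device_sd_speed,device_sd_cadence Device measurement noise SDs.
#' @param stopwatch_sd_s Stopwatch reading-error SD, seconds.
#' @param stopwatch_gross_prob,stopwatch_gross_sd_s Probability and SD of
#'   gross stopwatch misreads (user error).
#' @param age_mean,age_sd,prop_male Demographics.
#' @param age_speed_effect,age_cadence_effect Change in speed (m/s) and
#'   cadence (steps/min) per SD of age (negative: older is slower).
#' @param female_area_mean,female_area_sd Female body-area distribution, m^2.
#' @param male_area_shift Male body-area shift in female SDs.
#' @param fast_speed_factor,fast_cadence_factor Fast-pace scaling factors.
#' @param qor_interaction_beta Log-odds of good recovery per unit of the
#'   standardized speed x cadence interaction.
#' @return List of class `cohort_params`.
#' @export
cohort_params <- function(n = 77,
                          speed_mean = 1.2, speed_sd = 0.27,
                          cadence_mean = 111, cadence_sd = 11,
                          within_sd_speed = 0.03, within_sd_cadence = 2,
                          device_sd_speed = 0.02, device_sd_cadence = 1,
                          stopwatch_sd_s = 0.3,
                          stopwatch_gross_prob = 0.02,
                          stopwatch_gross_sd_s = 3,
                          age_mean = 66, age_sd = 13, prop_male = 0.6,
                          age_speed_effect = -0.09,
                          age_cadence_effect = -2.9,
                          female_area_mean = 0.62, female_area_sd = 0.05,
                          male_area_shift = 1.5,
                          fast_speed_factor = 1.25,
                          fast_cadence_factor = 1.14,
                          qor_interaction_beta = 0.8) {
  stopifnot(n >= 2, speed_sd >= 0, cadence_sd >= 0,
            abs(age_speed_effect) < speed_sd,
            abs(age_cadence_effect) < cadence_sd)
  structure(as.list(environment()), class = "cohort_params")
}

#' Simulate a cohort of subjects and walking trials
#'
#' Draws subject-level true gait metrics with age effects, then generates
#' two trials at each pace (regular, fast) per subject with within-subject
#' variation; each trial yields a device measurement (true value plus small
#' device noise) and a stopwatch measurement (walk time over the full
#' hallway plus reading error, occasionally grossly wrong). Frailty scores
#' increase monotonically as gait slows, and quality-of-recovery outcomes
#' are generated from the standardized speed-by-cadence interaction, so
#' downstream models have a recoverable signal.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @param hallway_length Stopwatch walk length, m.
#' @return List with `subjects` (one row per subject: demographics, body
#'   area, `fried_score`, `qor15`, `activity_level`) and `trials` (one row
#'   per subject x pace x repeat: `true_speed`, `device_speed`,
#'   `stopwatch_speed`, `true_cadence`, `device_cadence`).
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL,
                            hallway_length = 14) {
  if (!is.null(seed)) set.seed(seed)
  p <- params
  z_age <- rnorm(p$n)
  age <- round(p$age_mean + p$age_sd * z_age)
  male <- runif(p$n) < p$prop_male
  resid_speed_sd <- sqrt(p$speed_sd^2 - p$age_speed_effect^2)
  resid_cad_sd <- sqrt(p$cadence_sd^2 - p$age_cadence_effect^2)
  speed <- pmax(0.2, p$speed_mean + p$age_speed_effect * z_age +
                  rnorm(p$n, 0, resid_speed_sd))
  cadence <- pmax(40, p$cadence_mean + p$age_cadence_effect * z_age +
                    rnorm(p$n, 0, resid_cad_sd))
  area <- p$female_area_mean +
    ifelse(male, p$male_area_shift * p$female_area_sd, 0) +
    rnorm(p$n, 0, p$female_area_sd)

  # frailty rises as gait slows: latent slowness + noise binned to 0-5
  latent <- -(speed - p$speed_mean) / p$speed_sd + rnorm(p$n, 0, 0.8)
  fried <- pmin(5L, pmax(0L, as.integer(round(1.2 + latent))))
  # good recovery driven by the standardized speed x cadence interaction
  inter <- ((speed - p$speed_mean) / p$speed_sd) *
    ((cadence - p$cadence_mean) / p$cadence_sd)
  good <- runif(p$n) < stats::plogis(0.3 + p$qor_interaction_beta * inter)
  qor15 <- ifelse(good, sample(122:150, p$n, replace = TRUE),
                  sample(60:121, p$n, replace = TRUE))
  subjects <- tibble(
    id = seq_len(p$n), age = age, sex = ifelse(male, "M", "F"),
    body_area_m2 = area, fried_score = fried, qor15 = qor15,
    activity_level = sample(c("frequent", "occasional", "sedentary"),
                            p$n, replace = TRUE)
  )

  grid <- tidyr::expand_grid(id = seq_len(p$n),
                             pace = c("regular", "fast"),
                             trial = 1:2)
  pace_f_speed <- ifelse(grid$pace == "fast", p$fast_speed_factor, 1)
  pace_f_cad <- ifelse(grid$pace == "fast", p$fast_cadence_factor, 1)
  m <- nrow(grid)
  true_speed <- speed[grid$id] * pace_f_speed + rnorm(m, 0, p$within_sd_speed)
  true_cad <- cadence[grid$id] * pace_f_cad + rnorm(m, 0, p$within_sd_cadence)
  walk_time <- hallway_length / true_speed
  gross <- runif(m) < p$stopwatch_gross_prob
  sw_time <- walk_time + rnorm(m, 0, p$stopwatch_sd_s) +
    ifelse(gross, rnorm(m, 0, p$stopwatch_gross_sd_s), 0)
  sw_time <- pmax(sw_time, 1)
  trials <- dplyr::mutate(
    grid,
    true_speed = true_speed,
    device_speed = true_speed + rnorm(m, 0, p$device_sd_speed),
    stopwatch_speed = hallway_length / sw_time,
    true_cadence = true_cad,
    device_cadence = true_cad + rnorm(m, 0, p$device_sd_cadence)
  )
  list(subjects = subjects, trials = trials)
}
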