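#' @method tidy gait_speed_fit
#' @export
tidy.gait_speed_fit <- function(x, ...) {
  tibble(term = c("speed_m_s", "intercept_m"),
         estimate = c(x$speed_m_s, x$intercept_m))
}

#' @method glance gait_speed_fit
#' @export
glance.gait_speed_fit <- function(x, ...) {
  tibble(speed_m_s = x$speed_m_s, r2 = x$r2, n_kept = x$n_kept,
         trim_left = x$trim_left, trim_right = x$trim_right,
         converged = x$converged)
}

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble(term = "icc", estimate = x$icc, statistic = x$f, p_value = x$p)
}

#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble(icc = x$icc, p_value = x$p, statistic = x$f,
         df1 = x$df1, df2 = x$df2, form = x$form, n = x$n, k = x$k)
}

#' @method tidy loocv_result
#' @export
tidy.loocv_result <- function(x, ...) x$predictions

#' @method glance loocv_result
#' @export
glance.loocv_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, auc = x$auc,
         n = nrow(x$predictions), n_skipped = x$n_skipped)
}

#' @method tidy qor_interaction
#' @export
tidy.qor_interaction <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std_error = cf[, "Std. Error"], p_value = cf[, "Pr(>|z|)"],
         odds_ratio = exp(cf[, "Estimate"]))
}

#' @method glance qor_interaction
#' @export
glance.qor_interaction <- function(x, ...) {
  tibble(interaction_or = x$interaction_or, conf_low = x$conf_low,
         conf_high = x$conf_high, p_value = x$p,
         separation_flag = x$separation_flag, n = x$n)
}

#' @method tidy step_track
#' @export
tidy.step_track <- function(x, ...) x$track

#' @method glance step_track
#' @export
glance.step_track <- function(x, ...) {
  tibble(speed_m_s = x$speed_m_s, terminal_speed_m_s = x$terminal_speed_m_s,
         n_steps = nrow(x$track), n_gated = x$n_gated, r_meas = x$r_meas)
}
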