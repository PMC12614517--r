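#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_hline
#'   geom_abline labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a trimmed gait-speed fit
#'
#' Pelvis displacement against time, with trimmed samples greyed out and
#' the fitted line overlaid.
#'
#' @param object A `gait_speed_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot gait_speed_fit
#' @export
autoplot.gait_speed_fit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$time_s, y = .data$distance_m)) +
    geom_point(aes(colour = .data$kept), size = 0.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70")) +
    geom_abline(slope = object$speed_m_s, intercept = object$intercept_m,
                colour = "firebrick") +
    labs(x = "time (s)", y = "pelvis displacement (m)",
         title = sprintf("gait speed %.2f m/s, R² = %.3f",
                         object$speed_m_s, object$r2)) +
    theme_minimal()
}

#' Plot an SNR-max series with detected steps
#'
#' @param object An `snr_series`.
#' @param steps Optional `step_series` from [detect_steps()] to overlay.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot snr_series
#' @export
autoplot.snr_series <- function(object, steps = NULL, ...) {
  p <- ggplot(as_tibble(object),
              aes(x = .data$window_time_s, y = .data$snr_max)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "SNRmax") +
    theme_minimal()
  if (!is.null(steps) && nrow(steps)) {
    p <- p +
      geom_hline(yintercept = attr(steps, "threshold"),
                 linetype = "dashed", colour = "firebrick") +
      geom_point(data = as_tibble(steps),
                 aes(x = .data$step_time_s, y = .data$snr),
                 colour = "firebrick")
  }
  p
}

#' Plot a Kalman step track
#'
#' Observed and smoothed step positions over time; gated (rejected)
#' observations are hollow.
#'
#' @param object A `step_track` from [kalman_speed()].
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot step_track
#' @export
autoplot.step_track <- function(object, ...) {
  ggplot(object$track, aes(x = .data$time_s)) +
    geom_point(aes(y = .data$observed_m, shape = .data$used)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    geom_line(aes(y = .data$smoothed_m), colour = "firebrick") +
    labs(x = "step time (s)", y = "position along hallway (m)",
         title = sprintf("floor gait speed %.2f m/s", object$speed_m_s)) +
    theme_minimal()
}

#' Plot a test-retest scatter for an ICC result
#'
#' @param object An `icc_result` (two-trial table).
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot icc_result
#' @export
autoplot.icc_result <- function(object, ...) {
  d <- object$data
  names(d)[1:2] <- c("trial1", "trial2")
  ggplot(d, aes(x = .data$trial1, y = .data$trial2)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point() +
    labs(title = sprintf("ICC = %.2f (p = %.2g)", object$icc, object$p),
         x = "trial 1", y = "trial 2") +
    theme_minimal()
}

#' Plot a leave-one-out ROC curve
#'
#' @param object A `loocv_result`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot loocv_result
#' @export
autoplot.loocv_result <- function(object, ...) {
  ggplot(dplyr::arrange(object$roc, .data$fpr, .data$tpr),
         aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60",
                linetype = "dashed") +
    geom_line(colour = "firebrick") +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("LOOCV AUC = %.0f%%", 100 * object$auc)) +
    theme_minimal()
}
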