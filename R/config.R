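#' Walking-trial geometry
#'
#' Describes the hallway protocol: total walk length between the marked
#' lines, acceleration/deceleration zones at each end, and the central
#' monitored zone over which steady-state gait is quantified. Defaults match
#' a 14 m walk with 3.5 m tails and a 7 m monitored zone.
#'
#' @param hallway_length Total marked walk length in meters.
#' @param accel_zone Acceleration (and deceleration) zone length at each end, m.
#' @param monitored_zone Central steady-state zone length, m.
#' @param walk_pace Pace label, `"regular"` or `"fast"`.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(hallway_length = 14, accel_zone = 3.5,
                         monitored_zone = 7,
                         walk_pace = c("regular", "fast")) {
  walk_pace <- match.arg(walk_pace)
  stopifnot(hallway_length > 0, accel_zone >= 0, monitored_zone > 0)
  if (2 * accel_zone + monitored_zone > hallway_length) {
    abort("acceleration zones plus monitored zone exceed the hallway length")
  }
  structure(
    list(hallway_length = hallway_length, accel_zone = accel_zone,
         monitored_zone = monitored_zone, walk_pace = walk_pace),
    class = "trial_config"
  )
}

#' Default floor-sensor layout
#'
#' Seven single-axis accelerometers: six in a 2 x 3 grid (5.0 m along-hallway
#' by 3.5 m across-hallway spacing), with sensors 1-3 on the left wall wired
#' to the left data-acquisition unit and sensors 5-7 on the right wall wired
#' to the right unit. Sensor 4 is co-located with sensor 5 but wired to the
#' *left* unit: the cross-correlation of this co-located pair recovers the
#' clock offset between the two wireless units ([synchronize_record()]),
#' after which sensor 4 is discarded as redundant.
#'
#' @param hallway_length Hallway length in meters (grid is centered on it).
#' @return Tibble with columns `sensor`, `u_m` (along-hallway), `v_m`
#'   (across-hallway), `daq_group` (`"left"`/`"right"`).
#' @export
default_sensor_layout <- function(hallway_length = 14) {
  u <- hallway_length / 2 + c(-5, 0, 5)
  tibble(
    sensor = 1:7,
    u_m = c(u, u[1], u),
    v_m = c(rep(0, 3), rep(3.5, 4)),
    daq_group = c(rep("left", 3), "left", rep("right", 3))
  )
}
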