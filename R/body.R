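#' Body dimensions from a joint stream
#'
#' Per frame: torso length is the pelvis-to-neck distance; leg length is
#' hip-to-knee plus knee-to-ankle, averaged over the two sides; shoulder
#' width is the left-to-right shoulder distance. Each quantity is summarised
#' by its median over frames (robust to swing-phase geometry and tracking
#' noise). Body length is torso plus mean leg length; body area is shoulder
#' width times body length.
#'
#' @param stream A [joint_stream()] with shoulders, neck, pelvis, hips,
#'   knees and ankles tracked in at least `min_frames` frames.
#' @param min_frames Minimum number of frames with all required joints.
#' @return One-row tibble: `torso_m`, `leg_m`, `shoulder_width_m`,
#'   `body_length_m`, `body_area_m2`, `n_frames`.
#' @export
body_dimensions <- function(stream, min_frames = 10) {
  need <- c("pelvis", "neck", "shoulder_left", "shoulder_right",
            "hip_left", "knee_left", "ankle_left",
            "hip_right", "knee_right", "ankle_right")
  xyz <- lapply(setNames(need, need), function(j) joint_xyz(stream, j))
  dist3 <- function(a, b) sqrt(rowSums((a - b)^2))
  torso <- dist3(xyz$pelvis, xyz$neck)
  leg_l <- dist3(xyz$hip_left, xyz$knee_left) + dist3(xyz$knee_left, xyz$ankle_left)
  leg_r <- dist3(xyz$hip_right, xyz$knee_right) + dist3(xyz$knee_right, xyz$ankle_right)
  shoulder <- dist3(xyz$shoulder_left, xyz$shoulder_right)
  ok <- !is.na(torso) & !is.na(leg_l) & !is.na(leg_r) & !is.na(shoulder)
  if (sum(ok) < min_frames) {
    abort(sprintf("required joints tracked in %d frames; need >= %d",
                  sum(ok), min_frames))
  }
  torso_m <- median(torso[ok])
  leg_m <- median((leg_l[ok] + leg_r[ok]) / 2)
  shoulder_m <- median(shoulder[ok])
  body_length <- torso_m + leg_m
  tibble(
    torso_m = torso_m, leg_m = leg_m, shoulder_width_m = shoulder_m,
    body_length_m = body_length,
    body_area_m2 = shoulder_m * body_length,
    n_frames = sum(ok)
  )
}

#' Normalize body areas against a reference subgroup
#'
#' Standardizes every subject's body area by the mean and standard deviation
#' of a reference subgroup (conventionally the female subjects), yielding
#' z-scores in reference-SD units.
#'
#' @param areas Numeric vector of body areas (m^2).
#' @param reference_mask Logical vector marking the reference subgroup.
#' @return Numeric vector of z-scores, same length as `areas`.
#' @export
normalize_body_area <- function(areas, reference_mask) {
  stopifnot(length(areas) == length(reference_mask))
  ref <- areas[reference_mask & !is.na(areas)]
  if (length(ref) < 2) abort("reference subgroup must have at least 2 members")
  s <- sd(ref)
  if (!is.finite(s) || s <= 0) abort("reference subgroup has zero variance")
  (areas - mean(ref)) / s
}
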