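#' Joint names tracked by the body-tracking camera
#'
#' The 32 joints reported by the Azure-class body tracker, in SDK order.
#' Column names in a joint-stream CSV are `<joint>_<axis>` with axis one of
#' `x`, `y`, `z`.
#'
#' @format Character vector of length 32.
#' @export
kinect_joints <- c(
  "pelvis", "spine_navel", "spine_chest", "neck",
  "clavicle_left", "shoulder_left", "elbow_left", "wrist_left",
  "hand_left", "handtip_left", "thumb_left",
  "clavicle_right", "shoulder_right", "elbow_right", "wrist_right",
  "hand_right", "handtip_right", "thumb_right",
  "hip_left", "knee_left", "ankle_left", "foot_left",
  "hip_right", "knee_right", "ankle_right", "foot_right",
  "head", "nose", "eye_left", "ear_left", "eye_right", "ear_right"
)

joint_cols <- function(joint) paste0(joint, "_", c("x", "y", "z"))

#' Construct and validate a joint stream
#'
#' A joint stream is a tibble with a `time_s` column followed by
#' `<joint>_<x|y|z>` position columns in meters. Tracking dropouts are
#' encoded as `NA` for all three coordinates of a joint in a frame (never
#' zeros: zero is a legal coordinate). Validation enforces strictly
#' increasing timestamps, jointly present/missing coordinate triplets, at
#' least two frames, and the presence of the pelvis columns.
#'
#' @param data Data frame with `time_s` plus `<joint>_<axis>` columns.
#' @return A tibble of class `joint_stream`.
#' @seealso [read_joint_stream()], [write_joint_stream()]
#' @export
joint_stream <- function(data) {
  data <- as_tibble(data)
  if (!"time_s" %in% names(data)) {
    abort("joint stream must have a 'time_s' column", class = "walksense_format_error")
  }
  if (nrow(data) < 2) {
    abort("joint stream must have at least 2 frames", class = "walksense_format_error")
  }
  if (any(diff(data$time_s) <= 0) || anyNA(data$time_s)) {
    abort("timestamps must be strictly increasing", class = "walksense_format_error")
  }
  joints <- stream_joints(data)
  if (!"pelvis" %in% joints) {
    abort("pelvis columns (pelvis_x, pelvis_y, pelvis_z) are required",
          class = "walksense_format_error")
  }
  for (j in joints) {
    xyz <- as.matrix(data[joint_cols(j)])
    n_na <- rowSums(is.na(xyz))
    if (any(n_na > 0 & n_na < 3)) {
      abort(paste0("joint '", j, "' has frames with partially missing coordinates; ",
                   "dropouts must blank all three axes"),
            class = "walksense_format_error")
    }
  }
  class(data) <- c("joint_stream", class(data))
  data
}

# joints for which all three coordinate columns are present
stream_joints <- function(data) {
  axes <- c("_x", "_y", "_z")
  base <- unique(sub("_[xyz]$", "", setdiff(names(data), "time_s")))
  base[vapply(base, function(j) all(joint_cols(j) %in% names(data)), logical(1))]
}

# n x 3 coordinate matrix for one joint
joint_xyz <- function(stream, joint) {
  cols <- joint_cols(joint)
  if (!all(cols %in% names(stream))) {
    abort(paste0("joint '", joint, "' not present in stream"),
          class = "walksense_format_error")
  }
  as.matrix(stream[cols])
}

#' Read a joint stream from a wide CSV
#'
#' Expects a `time_s` column followed by `<joint>_<axis>` columns; `NA` (or
#' empty) cells mark tracking dropouts. If `units = "mm"` the coordinates are
#' converted to meters on read; this is the single unit-conversion point in
#' the package.
#'
#' @param path Path to the CSV file.
#' @param units Units of the coordinate columns, `"m"` (default) or `"mm"`.
#' @return A [joint_stream()] tibble.
#' @export
read_joint_stream <- function(path, units = c("m", "mm")) {
  units <- match.arg(units)
  data <- tibble::as_tibble(data.table::fread(path, data.table = FALSE))
  if (units == "mm") {
    pos <- setdiff(names(data), "time_s")
    data[pos] <- data[pos] / 1000
  }
  joint_stream(data)
}

#' Write a joint stream to CSV
#'
#' Inverse of [read_joint_stream()]; a write/read round trip reproduces every
#' numeric field exactly.
#'
#' @param stream A [joint_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_joint_stream <- function(stream, path) {
  write_csv_roundtrip(as.data.frame(stream), path)
  invisible(path)
}

# doubles written at %.17g round-trip bit-exactly, so write/read/write
# cycles are byte-stable — the general-purpose CSV writers only keep
# 15 significant digits
write_csv_roundtrip <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- "NA"
      s
    } else {
      as.character(col)
    }
  })
  writeLines(c(paste(names(df), collapse = ","),
               do.call(paste, c(cols, sep = ","))), path)
}

#' @export
print.joint_stream <- function(x, ...) {
  joints <- stream_joints(x)
  cat(sprintf("<joint_stream> %d frames, %d joints, %.2f s span\n",
              nrow(x), length(joints), diff(range(x$time_s))))
  NextMethod()
}
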