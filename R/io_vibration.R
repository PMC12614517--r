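#' Construct and validate a floor-vibration record
#'
#' A vibration record bundles uniformly sampled multi-channel floor
#' acceleration with its acquisition metadata: sample rate, per-sensor
#' hallway coordinates, data-acquisition (DAQ) group tags (each wireless DAQ
#' has an independent clock), and the co-located sensor pair used for clock
#' synchronization. No time column is stored: uniform sampling is asserted
#' through `sample_rate`.
#'
#' @param channels Data frame or matrix, one column per sensor (`ch1..chN`),
#'   equal lengths, dimensionless linear acceleration units.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param layout Sensor layout tibble as in [default_sensor_layout()]; must
#'   have one row per channel.
#' @param sync_pair Length-2 integer vector of co-located sensor indices; the
#'   two must belong to different DAQ groups, and the *first* is the
#'   redundant duplicate dropped after synchronization.
#' @param walk_line_v Across-hallway coordinate of the walking line, m.
#' @return A list of class `vibration_record` with elements `data` (tibble),
#'   `sample_rate`, `layout`, `sync_pair`, `walk_line_v`.
#' @export
vibration_record <- function(channels, sample_rate,
                             layout = default_sensor_layout(),
                             sync_pair = c(4L, 5L), walk_line_v = 1.75) {
  data <- as_tibble(as.data.frame(channels))
  names(data) <- paste0("ch", seq_along(data))
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    abort("sample_rate must be a positive scalar (Hz)",
          class = "walksense_format_error")
  }
  if (anyNA(data)) {
    abort("channels must be equal-length with no missing samples (ragged input?)",
          class = "walksense_format_error")
  }
  layout <- as_tibble(layout)
  if (nrow(layout) != ncol(data)) {
    abort(sprintf("layout declares %d sensors but %d channels supplied",
                  nrow(layout), ncol(data)),
          class = "walksense_format_error")
  }
  if (!is.null(sync_pair)) {
    sync_pair <- as.integer(sync_pair)
    stopifnot(length(sync_pair) == 2, all(sync_pair %in% seq_len(ncol(data))))
    if (layout$daq_group[sync_pair[1]] == layout$daq_group[sync_pair[2]]) {
      abort("sync_pair sensors must belong to different DAQ groups",
            class = "walksense_format_error")
    }
  }
  structure(
    list(data = data, sample_rate = sample_rate, layout = layout,
         sync_pair = sync_pair, walk_line_v = walk_line_v),
    class = "vibration_record"
  )
}

#' Read a vibration record from CSV plus JSON sidecar
#'
#' The CSV holds the channel samples (`ch1..chN`, no time column); the JSON
#' sidecar holds `sample_rate`, `layout` (records with `sensor`, `u_m`,
#' `v_m`, `daq_group`), `sync_pair`, and optionally `walk_line_v`.
#'
#' @param path CSV file of channel samples.
#' @param sidecar JSON metadata file.
#' @return A [vibration_record()].
#' @export
read_vibration <- function(path, sidecar) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- tibble::as_tibble(data.table::fread(path, data.table = FALSE))
  vibration_record(
    channels = data,
    sample_rate = meta$sample_rate,
    layout = as_tibble(meta$layout),
    sync_pair = meta$sync_pair,
    walk_line_v = meta$walk_line_v %||% 1.75
  )
}

#' Write a vibration record to CSV plus JSON sidecar
#'
#' Inverse of [read_vibration()]; round-tripping preserves every sample
#' bit-exactly.
#'
#' @param record A [vibration_record()].
#' @param path Output CSV path.
#' @param sidecar Output JSON path.
#' @return `path`, invisibly.
#' @export
write_vibration <- function(record, path, sidecar) {
  write_csv_roundtrip(as.data.frame(record$data), path)
  jsonlite::write_json(
    list(sample_rate = record$sample_rate,
         layout = record$layout,
         sync_pair = record$sync_pair,
         walk_line_v = record$walk_line_v),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.vibration_record <- function(x, ...) {
  cat(sprintf("<vibration_record> %d channels x %d samples @ %g Hz (%.2f s)\n",
              ncol(x$data), nrow(x$data), x$sample_rate,
              nrow(x$data) / x$sample_rate))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
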