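#' Preprocess floor-acceleration channels
#'
#' Each channel is linearly detrended (removing offset and slope), then
#' forward-backward filtered with a second-order Butterworth high-pass at
#' `hp_hz` (drift removal) and a second-order Butterworth low-pass at
#' `lp_hz` (mechanical-noise removal). Forward-backward application makes
#' the cascade zero-phase, so impulse timing — the quantity footstep
#' detection depends on — is not shifted.
#'
#' @param record A [vibration_record()]; `sample_rate` must exceed 500 Hz so
#'   the 250 Hz low-pass corner is below Nyquist.
#' @param hp_hz High-pass corner frequency, Hz.
#' @param lp_hz Low-pass corner frequency, Hz.
#' @param order Butterworth order per pass.
#' @return The record with filtered channels; attribute `preprocessed` set.
#' @export
preprocess_vibration <- function(record, hp_hz = 5, lp_hz = 250, order = 2) {
  fs <- record$sample_rate
  if (fs <= 500) abort("sample_rate must exceed 500 Hz for the 5-250 Hz band")
  n <- nrow(record$data)
  if (n < 12 * order) abort("channels shorter than the filter warm-up length")
  hp <- signal::butter(order, hp_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, lp_hz / (fs / 2), type = "low")
  i <- seq_len(n)
  record$data <- dplyr::mutate(record$data, dplyr::across(
    dplyr::everything(),
    function(x) {
      line <- ols_line(i, x)
      x <- x - (line$intercept + line$slope * i)
      signal::filtfilt(lp, signal::filtfilt(hp, x))
    }
  ))
  attr(record, "preprocessed") <- TRUE
  record
}

#' Synchronize the two DAQ clocks via the co-located sensor pair
#'
#' The two wireless data-acquisition units run on independent clocks. One
#' sensor of the `sync_pair` is physically co-located with a sensor wired to
#' the other unit, so the lag of the maximum cross-correlation between the
#' pair is the inter-clock offset. All channels of the second unit's group
#' are shifted by that lag, and the redundant duplicate sensor
#' (`sync_pair[1]`) is dropped from the record.
#'
#' @param record A preprocessed [vibration_record()] with a `sync_pair`.
#' @param max_lag_s Largest plausible clock offset searched, seconds.
#' @return List with `record` (synchronized, duplicate dropped) and `lag_s`
#'   (positive = the second group's channels lagged the first).
#' @export
synchronize_record <- function(record, max_lag_s = 2) {
  if (is.null(record$sync_pair)) abort("record has no sync_pair")
  i_ref <- record$sync_pair[1]
  i_dup <- record$sync_pair[2]
  x <- record$data[[i_ref]]
  y <- record$data[[i_dup]]
  if (sd(x) == 0 || sd(y) == 0) {
    abort("flat synchronization channel: no footsteps on the co-located pair")
  }
  n <- length(x)
  lag_range <- min(round(max_lag_s * record$sample_rate), n - 1)
  # FFT cross-correlation, zero-padded to a power of two: r(d) = sum_i x[i] y[i-d]
  m <- nextn(n + lag_range + 1, 2)
  X <- fft(c(x, numeric(m - n)))
  Y <- fft(c(y, numeric(m - n)))
  r <- Re(fft(X * Conj(Y), inverse = TRUE)) / m
  lags <- -lag_range:lag_range
  cc <- r[(lags %% m) + 1]  # r[(-d mod m)+1] pairs x[i] with y[i-d]... d = -lag
  d <- -lags[which.max(cc)]
  lag_s <- d / record$sample_rate

  move_group <- record$layout$daq_group[i_dup]
  for (j in which(record$layout$daq_group == move_group)) {
    record$data[[j]] <- shift_series(record$data[[j]], d)
  }
  keep <- setdiff(seq_len(ncol(record$data)), i_ref)
  record$data <- record$data[keep]
  names(record$data) <- paste0("ch", seq_along(keep))
  record$layout <- record$layout[keep, ]
  record$sync_pair <- NULL
  attr(record, "synchronized") <- TRUE
  list(record = record, lag_s = lag_s)
}

# advance (d > 0) or delay (d < 0) a series by d samples, zero-padded
shift_series <- function(x, d) {
  n <- length(x)
  if (d == 0) return(x)
  if (d > 0) c(x[(d + 1):n], numeric(min(d, n))) else c(numeric(min(-d, n)), x)[1:n]
}
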