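#' Continuous single-channel EEG/LFP recording
#'
#' Container for a continuous voltage trace.  The time convention throughout
#' the package is seconds from recording start plus `t0`; sample `i`
#' (0-based) covers the interval `[t0 + i/fs, t0 + (i+1)/fs)`.
#'
#' @param samples numeric vector of voltages (microvolts); must be finite.
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds.
#' @param channel_name channel label.
#' @return an object of class `eeg_recording` with fields `samples`,
#'   `sample_rate`, `t0` and `channel_name`.
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), 500)
#' rec
#' @export
eeg_recording <- function(samples, sample_rate, t0 = 0, channel_name = "EEG") {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` contains non-finite values", call. = FALSE)
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         t0 = as.numeric(t0), channel_name = as.character(channel_name)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d samples at %g Hz (%.3f s), t0 = %g s\n",
              x$channel_name, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$t0))
  invisible(x)
}

#' @export
length.eeg_recording <- function(x) length(x$samples)

# sample times (seconds)
rec_times <- function(rec) rec$t0 + (seq_along(rec$samples) - 1L) / rec$sample_rate

# index of the sample covering time t (0-based convention)
rec_index <- function(rec, t) as.integer(floor((t - rec$t0) * rec$sample_rate)) + 1L

#' Extract a time window from a recording
#'
#' @param rec an [eeg_recording()].
#' @param from,to window in seconds (absolute, i.e. on the `t0` axis).
#' @return an `eeg_recording` covering `[from, to)`.
#' @export
crop_recording <- function(rec, from, to) {
  i0 <- max(1L, rec_index(rec, from))
  i1 <- min(length(rec$samples), rec_index(rec, to) - 1L)
  if (i1 < i0) stop("empty crop window", call. = FALSE)
  eeg_recording(rec$samples[i0:i1], rec$sample_rate,
                t0 = rec$t0 + (i0 - 1L) / rec$sample_rate, rec$channel_name)
}

#' Zero-phase band-pass and notch filtering
#'
#' Emulates the acquisition chain: a 3--1000 Hz band-pass and notch filters
#' at the power-line frequency and its harmonics.  All filters are applied
#' forward-backward ([signal::filtfilt()]), so no group delay is added and
#' event latencies remain comparable to the raw trace.  The band-pass is
#' realised as a cascaded 2nd-order high-pass and 4th-order low-pass
#' Butterworth, which is numerically robust for low band edges relative to
#' the sampling rate.
#'
#' @param rec an [eeg_recording()].
#' @param band length-2 numeric, band edges in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param notch numeric vector of notch centre frequencies in Hz (default 60,
#'   120 and 180 Hz), or `NULL` to skip notch filtering.
#' @param notch_halfwidth half width of each notch stop band in Hz.
#' @return a filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, band = c(3, 1000), notch = c(60, 120, 180),
                             notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  nyq <- fs / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] || band[2] >= nyq)
    stop("`band` must satisfy 0 < low < high < sample_rate/2", call. = FALSE)
  x <- rec$samples
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  x <- signal::filtfilt(hp, x)
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  x <- signal::filtfilt(lp, x)
  for (f0 in notch) {
    if (f0 + notch_halfwidth >= nyq) next
    bs <- signal::butter(2, c(f0 - notch_halfwidth, f0 + notch_halfwidth) / nyq,
                         type = "stop")
    x <- signal::filtfilt(bs, x)
  }
  eeg_recording(x, fs, rec$t0, rec$channel_name)
}
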