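# Pulsogram construction and trajectory preprocessing.
#
# A pulsogram is a time-vs-time representation of an EEG response: snippets
# locked to each stimulus pulse (or detected spike) are stacked in
# chronological order.  The y axis is pulse-relative time in milliseconds,
# the x axis is the strip (anchor) index, and colour encodes voltage.

#' Build a pulsogram
#'
#' Extracts a `y_window` snippet around every anchor and stacks the snippets
#' in chronological order.  Anchors can be the pulses of a
#' [stim_protocol()], a [detect_spikes()] result, or a plain numeric vector
#' of times.  For pulse anchors, `extrapolate_s > 0` continues the anchor
#' grid at the pulse period beyond each train's end, so the pulse-locked
#' view extends into the post-stimulation tail.  Strips whose window exceeds
#' the recording are dropped with a message.  No smoothing is applied: each
#' strip is an exact re-slice of the raw samples.
#'
#' @param rec an [eeg_recording()].
#' @param anchors a `stim_protocol`, `spike_train`, or numeric vector of
#'   anchor times in seconds (strictly increasing).
#' @param y_window snippet window around each anchor, milliseconds
#'   (default -5 to 60 ms).
#' @param extrapolate_s for pulse anchors: seconds of post-train tail to
#'   cover with extrapolated anchors (0 = off).
#' @return object of class `pulsogram`: `values` (window samples x strips),
#'   `y_ms` (pulse-relative time of each row, ms), `anchor_times` (seconds),
#'   `anchor_kind` (`"pulse"` or `"spike"`), `fs`, and for pulse anchors the
#'   originating `protocol`.
#' @examples
#' p <- stim_protocol(10, n_epochs = 1, train_s = 2, break_s = 0, pre_s = 1)
#' rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 4, by = 1 / 3000)), 3000)
#' pg <- build_pulsogram(rec, p)
#' dim(pg$values)
#' @export
build_pulsogram <- function(rec, anchors, y_window = c(-5, 60),
                            extrapolate_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  protocol <- NULL
  if (inherits(anchors, "stim_protocol")) {
    protocol <- anchors
    at <- anchors$pulse_onsets
    kind <- "pulse"
    if (extrapolate_s > 0) {
      period <- 1 / anchors$frequency
      extra <- unlist(lapply(anchors$epoch_windows, function(w) {
        last <- max(at[at >= w[1] & at < w[2]])
        last + period * seq_len(floor(extrapolate_s / period))
      }))
      at <- sort(c(at, extra))
    }
  } else if (inherits(anchors, "spike_train")) {
    at <- anchors$spike_times
    kind <- "spike"
  } else {
    at <- as.numeric(anchors)
    kind <- "pulse"
  }
  if (!length(at)) stop("empty anchor set", call. = FALSE)
  if (any(diff(at) <= 0)) stop("anchor times must be strictly increasing",
                               call. = FALSE)
  fs <- rec$sample_rate
  off <- seq(round(y_window[1] / 1000 * fs), round(y_window[2] / 1000 * fs))
  y_ms <- off / fs * 1000
  idx0 <- round((at - rec$t0) * fs) + 1L
  lo <- idx0 + off[1]
  hi <- idx0 + off[length(off)]
  keep <- lo >= 1L & hi <= length(rec$samples)
  if (!all(keep))
    message(sprintf("dropping %d strip(s) whose window exceeds the recording",
                    sum(!keep)))
  if (!any(keep)) stop("no strip fits within the recording", call. = FALSE)
  idx0 <- idx0[keep]
  values <- vapply(idx0, function(i) rec$samples[i + off], numeric(length(off)))
  structure(
    list(values = values, y_ms = y_ms, anchor_times = at[keep],
         anchor_kind = kind, fs = fs, protocol = protocol),
    class = "pulsogram")
}

#' @export
print.pulsogram <- function(x, ...) {
  cat(sprintf("<pulsogram> %d strips (%s-anchored), y = %.1f..%.1f ms at %g Hz\n",
              ncol(x$values), x$anchor_kind, min(x$y_ms), max(x$y_ms), x$fs))
  invisible(x)
}

#' @export
plot.pulsogram <- function(x, main = "Pulsogram", ...) {
  image(x = x$anchor_times, y = x$y_ms, z = t(x$values),
        col = hcl.colors(64, "RdBu", rev = TRUE),
        xlab = "train time (s)", ylab = "pulse time (ms)", main = main, ...)
  box()
  invisible(x)
}

#' Detect interictal spikes
#'
#' Positive-going EEG discharges are detected as local maxima of the
#' smoothed trace exceeding `k_mad` median absolute deviations.  The MAD is
#' taken about zero and unscaled (`median(|x|)`), matching the convention of
#' the spike-anchored pulsogram; smoothing is a 10 ms 2nd-order
#' Savitzky-Golay filter.  Of any two peaks closer than the refractory
#' interval the later one is discarded, keeping only the first peak of a
#' multi-phasic discharge.
#'
#' @param rec an [eeg_recording()].
#' @param k_mad threshold in MAD units (default 6).
#' @param refractory_s minimum inter-spike interval in seconds (default 20 ms).
#' @param smooth_s Savitzky-Golay smoothing window in seconds (default 10 ms).
#' @return object of class `spike_train`: `spike_times` (seconds),
#'   `threshold` (uV), `mad` (uV), `peak_amplitudes` (smoothed-trace peak
#'   values, uV).
#' @export
detect_spikes <- function(rec, k_mad = 6, refractory_s = 0.02,
                          smooth_s = 0.01) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$samples
  m <- median(abs(x))
  if (m == 0)
    stop("MAD of the recording is zero; supply a manual threshold by scaling the data",
         call. = FALSE)
  thr <- k_mad * m
  xs <- sg_smooth(x, smooth_s, rec$sample_rate)
  n <- length(xs)
  is_max <- c(FALSE, xs[2:(n - 1)] > xs[1:(n - 2)] & xs[2:(n - 1)] >= xs[3:n],
              FALSE)
  peaks <- which(is_max & xs > thr)
  kept <- integer(0)
  last_t <- -Inf
  for (p in peaks) {
    tp <- (p - 1L) / rec$sample_rate
    if (tp - last_t >= refractory_s) {
      kept <- c(kept, p)
      last_t <- tp
    }
  }
  structure(
    list(spike_times = rec$t0 + (kept - 1L) / rec$sample_rate,
         threshold = thr, mad = m, peak_amplitudes = xs[kept]),
    class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes, threshold %.2f uV (mad %.2f uV)\n",
              length(x$spike_times), x$threshold, x$mad))
  invisible(x)
}

#' Instantaneous-power pulsogram in dB
#'
#' Estimates instantaneous power as the squared Hilbert envelope of the EEG,
#' smooths it (10 ms 2nd-order Savitzky-Golay), builds a pulsogram of the
#' smoothed power, and converts to dB relative to a per-row (pulse-time)
#' reference so that the average reference-region power is ~0 dB at every
#' pulse time.  For pulse anchors the reference region is the induction
#' phase (strips before the divergent point); for spike anchors it is the
#' 60 s window leading into the divergent point.  When no markers are given
#' a reference window in seconds can be supplied instead.
#'
#' @param rec an [eeg_recording()].
#' @param anchors as in [build_pulsogram()].
#' @param markers optional [phase_markers()] defining the reference region.
#' @param reference_window optional numeric `c(start, stop)` in seconds:
#'   strips anchored inside it form the reference (used when `markers` is
#'   `NULL`).
#' @param y_window snippet window in ms.
#' @param smooth_s power smoothing window in seconds.
#' @param interictal_window reference span before the divergent point for
#'   spike anchors, seconds.
#' @return object of class `power_pulsogram` (also `pulsogram`): dB
#'   `values`, `reference_power` (per-row linear power at 0 dB),
#'   `reference_strips` (indices).
#' @export
power_pulsogram <- function(rec, anchors, markers = NULL,
                            reference_window = NULL, y_window = c(-5, 60),
                            smooth_s = 0.01, interictal_window = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  pow <- hilbert_envelope(rec$samples)^2
  pow <- sg_smooth(pow, smooth_s, rec$sample_rate)
  pow[pow < 0] <- 0
  prec <- eeg_recording(pow, rec$sample_rate, rec$t0, rec$channel_name)
  pg <- build_pulsogram(prec, anchors, y_window = y_window)
  if (!is.null(markers)) {
    stopifnot(inherits(markers, "phase_markers"))
    if (pg$anchor_kind == "pulse") {
      di <- if (is.na(markers$divergent)) Inf else markers$divergent
      ref <- which(pg$anchor_times >= markers$epoch_start &
                     pg$anchor_times < di)
    } else {
      if (is.na(markers$divergent))
        stop("spike-anchored reference needs a divergent point", call. = FALSE)
      ref <- which(pg$anchor_times >= markers$divergent - interictal_window &
                     pg$anchor_times < markers$divergent)
    }
  } else if (!is.null(reference_window)) {
    ref <- which(pg$anchor_times >= reference_window[1] &
                   pg$anchor_times < reference_window[2])
  } else {
    stop("supply `markers` or `reference_window` for the 0 dB reference",
         call. = FALSE)
  }
  if (!length(ref)) stop("reference region contains no strips", call. = FALSE)
  ref_pow <- rowMeans(pg$values[, ref, drop = FALSE])
  ref_pow[ref_pow <= 0] <- min(ref_pow[ref_pow > 0], na.rm = TRUE)
  db <- 10 * log10(sweep(pg$values, 1L, ref_pow, `/`) +
                     .Machine$double.eps)
  pg$values <- db
  pg$reference_power <- ref_pow
  pg$reference_strips <- ref
  class(pg) <- c("power_pulsogram", "pulsogram")
  pg
}

#' @export
print.power_pulsogram <- function(x, ...) {
  cat(sprintf("<power_pulsogram> %d strips, y = %.1f..%.1f ms, %d reference strips (0 dB)\n",
              ncol(x$values), min(x$y_ms), max(x$y_ms),
              length(x$reference_strips)))
  invisible(x)
}

#' Trajectory preprocessing of a pulsogram
#'
#' Three stages, in order: (1) smoothing along the pulse-time (y) dimension
#' with a 2 ms 2nd-order Savitzky-Golay filter; (2) per-strip normalisation
#' by the regularised scale `kappa[x] = sqrt((v[x] + v0) / 2)`, where `v[x]`
#' is the strip power (sum of squared samples over -5..50 ms) and `v0` is
#' the mean of `v` over stimulation strips -- this attenuates spurious
#' high-power strips without blowing up quiet ones; (3) smoothing along the
#' strip (x) dimension with a 2 s 2nd-order Savitzky-Golay filter.  The
#' output is restricted to the -5..50 ms analysis window and is treated as
#' an n-dimensional trajectory over strips by the trajectory analyses.
#'
#' @param p a [build_pulsogram()] result.
#' @param stim_strips optional indices of strips within stimulation (used
#'   for `v0`); defaults to strips whose anchors fall inside the protocol's
#'   train windows, or to all strips for spike-anchored pulsograms.
#' @param y_crop analysis window in ms.
#' @param y_smooth_s,x_smooth_s Savitzky-Golay window lengths (seconds of
#'   pulse time / of train time).
#' @return object of class `trajectory_matrix`: `values` (cropped rows x
#'   strips), `kappa`, `strip_power` (`v[x]`), `mean_power` (`v0`),
#'   `n_stim`, `times` (strip anchor times), `y_ms`, `strip_rate` (strips/s).
#' @export
preprocess_trajectory <- function(p, stim_strips = NULL, y_crop = c(-5, 50),
                                  y_smooth_s = 0.002, x_smooth_s = 2) {
  stopifnot(inherits(p, "pulsogram"))
  if (min(p$y_ms) > y_crop[1] || max(p$y_ms) < y_crop[2])
    stop(sprintf("pulsogram must cover %g..%g ms", y_crop[1], y_crop[2]),
         call. = FALSE)
  V <- apply(p$values, 2L, sg_smooth, width_s = y_smooth_s, rate = p$fs)
  rows <- p$y_ms >= y_crop[1] & p$y_ms <= y_crop[2]
  V <- V[rows, , drop = FALSE]
  if (is.null(stim_strips)) {
    stim_strips <- if (!is.null(p$protocol)) {
      which(vapply(p$anchor_times, function(a)
        any(vapply(p$protocol$epoch_windows,
                   function(w) a >= w[1] && a < w[2], logical(1))),
        logical(1)))
    } else seq_len(ncol(V))
  }
  if (!length(stim_strips)) stop("no stimulation strips", call. = FALSE)
  v <- colSums(V^2)
  v0 <- mean(v[stim_strips])
  if (v0 == 0) stop("degenerate recording: zero mean strip power", call. = FALSE)
  kappa <- sqrt((v + v0) / 2)
  V <- sweep(V, 2L, kappa, `/`)
  strip_rate <- if (ncol(V) >= 2L) 1 / median(diff(p$anchor_times)) else NA_real_
  if (ncol(V) >= 7L && is.finite(strip_rate)) {
    # smooth within contiguous anchor blocks only: strips separated by a
    # break (inter-train gap) must not blend into each other
    gaps <- which(diff(p$anchor_times) > 3 / strip_rate)
    starts <- c(1L, gaps + 1L)
    ends <- c(gaps, ncol(V))
    for (b in seq_along(starts)) {
      cols <- starts[b]:ends[b]
      if (length(cols) >= 7L)
        V[, cols] <- t(apply(V[, cols, drop = FALSE], 1L, sg_smooth,
                             width_s = x_smooth_s, rate = strip_rate))
    }
  }
  structure(
    list(values = V, kappa = kappa, strip_power = v, mean_power = v0,
         n_stim = length(stim_strips), times = p$anchor_times,
         y_ms = p$y_ms[rows], strip_rate = strip_rate,
         anchor_kind = p$anchor_kind),
    class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix> %d strips x %d dims, v0 = %.3g, %d stimulation strips\n",
              ncol(x$values), nrow(x$values), x$mean_power, x$n_stim))
  invisible(x)
}

#' Restrict a trajectory to a time window
#'
#' @param tm a [preprocess_trajectory()] result.
#' @param window numeric `c(start, stop)` in seconds (strip anchor times).
#' @return a `trajectory_matrix` containing the strips anchored in
#'   `[start, stop)`.
#' @export
window_trajectory <- function(tm, window) {
  stopifnot(inherits(tm, "trajectory_matrix"))
  keep <- tm$times >= window[1] & tm$times < window[2]
  if (!any(keep)) stop("no strips in window", call. = FALSE)
  tm$values <- tm$values[, keep, drop = FALSE]
  tm$kappa <- tm$kappa[keep]
  tm$strip_power <- tm$strip_power[keep]
  tm$times <- tm$times[keep]
  tm
}

#' Reverberant-vs-induction power change per latency band
#'
#' Mean dB change of the early (immediate-discharge, 0--20 ms) and late
#' (secondary-discharge, 20--50 ms) bands between the reverberant phase
#' (divergent to paroxysmal point, or to stimulation end when no paroxysmal
#' point exists) and the induction phase (epoch start to divergent point).
#' For spike-anchored pulsograms use `late = c(15, 50)`.
#'
#' @param pp a [power_pulsogram()].
#' @param markers a [phase_markers()] with a divergent point.
#' @param stim_end stimulation end time in seconds (bounds the reverberant
#'   phase when the paroxysmal point is absent).
#' @param early,late latency bands in ms.
#' @return list with `delta_early` and `delta_late` (dB).
#' @export
delta_power <- function(pp, markers, stim_end, early = c(0, 20),
                        late = c(20, 50)) {
  stopifnot(inherits(pp, "power_pulsogram"), inherits(markers, "phase_markers"))
  if (is.na(markers$divergent))
    stop("delta_power needs a divergent point", call. = FALSE)
  di <- markers$divergent
  px <- if (!is.na(markers$paroxysmal)) markers$paroxysmal else stim_end
  ind <- which(pp$anchor_times >= markers$epoch_start & pp$anchor_times < di)
  rev <- which(pp$anchor_times >= di & pp$anchor_times < px)
  if (length(ind) < 1L || length(rev) < 1L)
    stop("induction or reverberant phase shorter than one strip", call. = FALSE)
  # band averages are taken in the linear power domain (area under the
  # power curve over the band), then expressed as a dB change
  band_mean <- function(strips, band) {
    rows <- pp$y_ms >= band[1] & pp$y_ms < band[2]
    mean(10^(pp$values[rows, strips, drop = FALSE] / 10))
  }
  list(delta_early = 10 * log10(band_mean(rev, early) / band_mean(ind, early)),
       delta_late = 10 * log10(band_mean(rev, late) / band_mean(ind, late)))
}
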