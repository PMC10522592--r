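#' Spectrogram of a recording
#'
#' Short-time Fourier power spectrogram with a Hann window, scaled as a
#' one-sided power spectral density (`1 / (fs * sum(w^2))`, non-DC bins
#' doubled) so that the frequency-integrated power of a frame matches the
#' time-domain variance (Parseval).  Window and overlap default to the
#' acquisition-matched 0.33 s window with 87.5% overlap, giving a hop of
#' `window_s * (1 - overlap)` = 41.25 ms.
#'
#' The FFT is zero-padded so that power is evaluated on a frequency grid of
#' at most `df_hz` spacing; with the default 1 Hz grid the stimulation
#' harmonics (integer frequencies) sit on bin centres, which keeps the
#' +-1 Hz harmonic bands of [harmonic_decomposition()] meaningful at any
#' window length.
#'
#' @param rec an [eeg_recording()].
#' @param window_s analysis window length in seconds.
#' @param overlap fractional overlap between consecutive windows in `[0, 1)`.
#' @param df_hz target frequency-grid spacing in Hz (zero-padding; the
#'   spectral resolution itself is set by `window_s`).
#' @return object of class `spectral_decomposition` with fields `times`
#'   (window-centre seconds), `freqs` (Hz), `power` (time x frequency PSD
#'   matrix), `hop_s`, and empty per-time summaries (`harmonic_power`,
#'   `total_power`, `nonharmonic_power`) until [harmonic_decomposition()]
#'   fills them.
#' @export
compute_spectrogram <- function(rec, window_s = 0.33, overlap = 0.875,
                                df_hz = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  n <- round(window_s * fs)
  if (n > length(rec$samples))
    stop("window longer than the recording", call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  hop <- max(1L, round(n * (1 - overlap)))
  nfft <- max(n, 2L * floor(fs / df_hz / 2))
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  sg <- signal::specgram(rec$samples, n = nfft, Fs = fs, window = w,
                         overlap = n - hop)
  P <- Mod(sg$S)^2 / (fs * sum(w^2))
  P[-1L, ] <- 2 * P[-1L, ]                 # one-sided (DC not doubled)
  n_frames <- ncol(P)
  centres <- rec$t0 + ((seq_len(n_frames) - 1L) * hop + (n - 1) / 2) / fs
  structure(
    list(times = centres, freqs = as.numeric(sg$f), power = t(P),
         hop_s = window_s * (1 - overlap), window_s = window_s,
         harmonic_power = NULL, total_power = NULL, nonharmonic_power = NULL,
         f0 = NA_real_),
    class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("<spectral_decomposition> %d frames x %d freqs (0-%.0f Hz), hop %.4g s\n",
              length(x$times), length(x$freqs), max(x$freqs), x$hop_s))
  if (!is.null(x$harmonic_power))
    cat(sprintf("  harmonic summaries at f0 = %g Hz\n", x$f0))
  invisible(x)
}

#' Harmonic vs non-harmonic power decomposition
#'
#' Splits the per-frame spectrogram power into the part carried by the
#' stimulation frequency and its harmonics (`k * f0 +- halfwidth`, all `k`
#' with `k * f0 <= fmax`, overlapping bands unioned) and the remainder.
#' Total power sums all bins with `0 < f <= fmax` (the DC bin is excluded),
#' so `total = harmonic + nonharmonic` holds exactly at every frame.
#'
#' @param spec a [compute_spectrogram()] result.
#' @param f0 fundamental stimulation frequency in Hz.
#' @param halfwidth harmonic band half width in Hz (band edges inclusive).
#' @param fmax upper frequency bound for the power summaries in Hz.
#' @return the input with `harmonic_power`, `total_power` and
#'   `nonharmonic_power` (per-frame vectors) filled in.
#' @export
harmonic_decomposition <- function(spec, f0, halfwidth = 1, fmax = 200) {
  stopifnot(inherits(spec, "spectral_decomposition"))
  stop_if_not_scalar_pos(f0, "f0")
  if (f0 >= fmax) stop("f0 must be below fmax", call. = FALSE)
  f <- spec$freqs
  in_range <- f > 0 & f <= fmax
  harm <- rep(FALSE, length(f))
  for (k in seq_len(floor(fmax / f0)))
    harm <- harm | (f >= k * f0 - halfwidth & f <= k * f0 + halfwidth)
  harm <- harm & in_range
  spec$total_power <- rowSums(spec$power[, in_range, drop = FALSE])
  spec$harmonic_power <- rowSums(spec$power[, harm, drop = FALSE])
  spec$nonharmonic_power <- spec$total_power - spec$harmonic_power
  spec$f0 <- f0
  spec
}

#' Event-aligned time rescaling and averaging
#'
#' Rescales each trace piecewise-linearly so that its event boundaries land
#' on a common grid, then averages pointwise.  Used to average power or
#' harmonic-fraction traces across seizures whose phases have different
#' durations (e.g. 15 s pre-stimulation | stimulation-to-paroxysmal |
#' paroxysmal-to-stimulation-end | 15 s post-stimulation).  When `groups` is
#' given, traces are first averaged within each group (e.g. within each
#' animal) and the group means are then averaged.
#'
#' @param traces list of traces, each a list with numeric `times` and
#'   `values` of equal length.
#' @param boundaries list of numeric vectors (one per trace): the segment
#'   boundary times, all of the same length `m >= 2`, strictly increasing,
#'   inside the trace's time span.  Traces with missing (non-finite)
#'   boundaries are excluded with a message.
#' @param n_grid points per segment on the common axis.
#' @param groups optional vector (length = number of traces) of group ids
#'   for hierarchical averaging.
#' @return list with `axis` (common rescaled axis, in units of segment index
#'   0..m-1), `mean` (averaged trace), `matrix` (rescaled traces x grid) and
#'   `used` (indices of traces that entered the average).
#' @export
event_aligned_average <- function(traces, boundaries, n_grid = 100L,
                                  groups = NULL) {
  stopifnot(length(traces) == length(boundaries))
  m <- unique(vapply(boundaries, length, integer(1)))
  if (length(m) != 1L || m < 2L)
    stop("all boundary vectors must share one length >= 2", call. = FALSE)
  ok <- vapply(seq_along(traces), function(i) {
    b <- boundaries[[i]]
    all(is.finite(b)) && !any(diff(b) <= 0)
  }, logical(1))
  if (!all(ok))
    message(sprintf("excluding %d trace(s) with missing or non-monotone boundaries",
                    sum(!ok)))
  if (!any(ok)) stop("no usable traces", call. = FALSE)
  n_seg <- m - 1L
  # common axis: segment index fraction, endpoint-preserving per segment
  axis <- unlist(lapply(seq_len(n_seg), function(s)
    s - 1 + seq(0, 1, length.out = n_grid + 1L)[-(n_grid + 1L)]))
  axis <- c(axis, n_seg)
  resc <- lapply(which(ok), function(i) {
    tr <- traces[[i]]; b <- boundaries[[i]]
    seg <- pmin(floor(axis), n_seg - 1L)
    frac <- axis - seg
    tq <- b[seg + 1L] + frac * (b[seg + 2L] - b[seg + 1L])
    approx(tr$times, tr$values, xout = tq, rule = 2)$y
  })
  M <- do.call(rbind, resc)
  if (!is.null(groups)) {
    g <- groups[ok]
    gm <- t(vapply(unique(g),
                   function(k) colMeans(M[g == k, , drop = FALSE]),
                   numeric(ncol(M))))
    avg <- colMeans(gm)
  } else avg <- colMeans(M)
  list(axis = axis, mean = avg, matrix = M, used = which(ok))
}

#' Alignment boundaries for the four-segment seizure average
#'
#' Convenience builder for the canonical alignment: 15 s pre-stimulation,
#' stimulation start to paroxysmal point, paroxysmal point to stimulation
#' end, 15 s post-stimulation.
#'
#' @param markers a [phase_markers()] with a paroxysmal point.
#' @param stim_window numeric `c(start, end)` of the train in seconds.
#' @param pre_s,post_s baseline spans in seconds.
#' @return numeric vector of 5 boundary times (contains `NA` when the
#'   paroxysmal point is absent, letting [event_aligned_average()] exclude
#'   the trace).
#' @export
seizure_alignment_boundaries <- function(markers, stim_window,
                                         pre_s = 15, post_s = 15) {
  stopifnot(inherits(markers, "phase_markers"))
  c(stim_window[1] - pre_s, stim_window[1], markers$paroxysmal,
    stim_window[2], stim_window[2] + post_s)
}
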