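# Automated detection of the transition points of ictogenesis.  The
# detectors operationalise the qualitative signatures: a sharp sustained
# rise of 20-50 ms post-pulse power marks the divergent point; collapse of
# the stimulation-harmonic fraction together with a broad power rise marks
# the paroxysmal point; return of total power to the pre-stimulation
# baseline marks the seizure end.

#' Detector thresholds and sustain windows
#'
#' All transition-detector tuning constants in one place.  Values are
#' operational choices anchored to the qualitative spectral signatures, not
#' measured quantities.
#'
#' @param baseline_s early-stimulation baseline for the divergent detector
#'   (first seconds of stimulation strips).
#' @param k_sd divergent/paroxysmal threshold in baseline SD units.
#' @param sustain_divergent_s time the late-band power must stay above
#'   threshold.
#' @param harmonic_drop paroxysmal trigger: harmonic fraction below this
#'   multiple of its running median.
#' @param sustain_paroxysmal_s time the harmonic collapse must persist.
#' @param runmed_s span of the causal running median of the harmonic
#'   fraction.
#' @param k_sd_end seizure-end threshold in pre-stimulation SD units.
#' @param sustain_end_s time total power must stay at baseline.
#' @param prestim_s pre-stimulation baseline span.
#' @param late_smooth_s moving-average span (seconds of train time) applied
#'   to the late-band power series before thresholding; suppresses
#'   strip-to-strip background fluctuation without blurring the sharp
#'   secondary-discharge onset.
#' @return a list of detector options.
#' @export
transition_options <- function(baseline_s = 2, k_sd = 3,
                               sustain_divergent_s = 1, harmonic_drop = 0.5,
                               sustain_paroxysmal_s = 0.5, runmed_s = 5,
                               k_sd_end = 2, sustain_end_s = 2,
                               prestim_s = 15, late_smooth_s = 0.5) {
  as.list(environment())
}

# causal running median over the preceding `k` entries (inclusive)
causal_runmed <- function(x, k) {
  n <- length(x)
  vapply(seq_len(n), function(i) median(x[max(1L, i - k + 1L):i]), numeric(1))
}

#' Detect the transition points of one stimulation epoch
#'
#' Runs the three detectors on an epoch:
#' * divergent point: first strip whose 20--50 ms post-pulse mean power (dB)
#'   exceeds the early-stimulation baseline mean + `k_sd` SD, sustained for
#'   `sustain_divergent_s`;
#' * paroxysmal point: first spectrogram frame where the harmonic fraction
#'   falls below `harmonic_drop` of its causal running median while total
#'   power exceeds the pre-stimulation baseline + `k_sd` SD, sustained for
#'   `sustain_paroxysmal_s`;
#' * seizure end: first post-paroxysmal frame where total power returns
#'   below the pre-stimulation baseline + `k_sd_end` SD for
#'   `sustain_end_s`.
#'
#' Absent transitions yield absent (`NA`) markers; a paroxysmal candidate
#' without a preceding divergent point is discarded so returned markers
#' always satisfy the ordering invariant.
#'
#' @param spec a [harmonic_decomposition()] result covering the epoch
#'   (including the pre-stimulation baseline).
#' @param pp a [power_pulsogram()] of the epoch's pulse-anchored strips,
#'   referenced to the early-stimulation window.
#' @param stim_window numeric `c(start, end)` of the train, seconds.
#' @param options a [transition_options()] list.
#' @param late latency band of the secondary discharge, ms.
#' @return a [phase_markers()].
#' @export
detect_transitions <- function(spec, pp, stim_window,
                               options = transition_options(),
                               late = c(20, 50)) {
  stopifnot(inherits(spec, "spectral_decomposition"),
            inherits(pp, "power_pulsogram"))
  if (is.null(spec$harmonic_power))
    stop("run harmonic_decomposition() on the spectrogram first", call. = FALSE)
  o <- options
  s0 <- stim_window[1]; s1 <- stim_window[2]

  ## divergent point, from the power pulsogram
  stim_strips <- which(pp$anchor_times >= s0 & pp$anchor_times < s1)
  if (length(stim_strips) < 3L)
    stop("epoch contains too few stimulation strips", call. = FALSE)
  rows <- pp$y_ms >= late[1] & pp$y_ms < late[2]
  L <- colMeans(pp$values[rows, stim_strips, drop = FALSE])
  at <- pp$anchor_times[stim_strips]
  strip_rate <- 1 / median(diff(at))
  L <- runmean_partial(L, max(1L, round(o$late_smooth_s * strip_rate)))
  bl <- which(at < s0 + o$baseline_s)
  if (length(bl) < 2L) stop("epoch shorter than the baseline window", call. = FALSE)
  thr <- mean(L[bl]) + o$k_sd * sd(L[bl])
  k_div <- max(1L, round(o$sustain_divergent_s * strip_rate))
  cand <- L > thr
  cand[bl] <- FALSE
  i_div <- first_sustained(cand, k_div)
  if (!is.na(i_div)) {
    # hysteresis onset refinement: the sustained run certifies the event;
    # the onset is walked back while the ramping late-band power still
    # exceeds a lower (mean + 1 SD) threshold
    thr_lo <- mean(L[bl]) + sd(L[bl])
    j <- i_div
    while (j > max(bl) + 1L && L[j - 1L] > thr_lo) j <- j - 1L
    i_div <- j
  }
  divergent <- if (is.na(i_div)) NA_real_ else at[i_div]

  ## paroxysmal point, from the harmonic decomposition
  tt <- spec$times
  hf <- spec$harmonic_power / pmax(spec$total_power, .Machine$double.xmin)
  frame_rate <- 1 / spec$hop_s
  # total power smoothed over ~1 s so amplitude-modulated ictal bursting
  # does not momentarily drop below the power criterion
  tot <- runmean_partial(spec$total_power, max(1L, round(frame_rate)))
  pre <- which(tt >= s0 - o$prestim_s & tt < s0)
  if (length(pre) < 2L) stop("no pre-stimulation baseline frames", call. = FALSE)
  base_mu <- mean(tot[pre])
  base_sd <- sd(tot[pre])
  stim_frames <- which(tt >= s0)
  rm_hf <- rep(NA_real_, length(tt))
  rm_hf[stim_frames] <- causal_runmed(hf[stim_frames],
                                      max(3L, round(o$runmed_s * frame_rate)))
  cond <- hf < o$harmonic_drop * rm_hf & tot > base_mu + o$k_sd * base_sd
  cond[tt < s0 + o$baseline_s] <- FALSE
  k_px <- max(1L, round(o$sustain_paroxysmal_s * frame_rate))
  i_px <- first_sustained(cond, k_px)
  paroxysmal <- if (is.na(i_px)) NA_real_ else tt[i_px]
  if (!is.na(paroxysmal) &&
      (is.na(divergent) || paroxysmal <= divergent)) paroxysmal <- NA_real_

  ## seizure end, from total power
  seizure_end <- NA_real_
  if (!is.na(paroxysmal)) {
    post <- which(tt > paroxysmal)
    quiet <- tot[post] < base_mu + o$k_sd_end * base_sd
    k_end <- max(1L, round(o$sustain_end_s * frame_rate))
    i_end <- first_sustained(quiet, k_end)
    if (!is.na(i_end)) seizure_end <- tt[post[i_end]]
  }
  phase_markers(epoch_start = s0, divergent = divergent,
                paroxysmal = paroxysmal, seizure_end = seizure_end)
}

#' Analyse one epoch of a recording
#'
#' Convenience wrapper: crops the epoch (pre-stimulation baseline, train and
#' post-train tail), computes the harmonic spectrogram and the
#' early-referenced power pulsogram, and runs [detect_transitions()].
#'
#' @param rec an [eeg_recording()].
#' @param protocol a [stim_protocol()].
#' @param epoch epoch index (1-based).
#' @param options a [transition_options()] list.
#' @param tail_s post-train tail to include, seconds (bounded by the break).
#' @return list with `markers` ([phase_markers()]), `label` (response
#'   class), `spec`, `pp`.
#' @export
analyze_epoch <- function(rec, protocol, epoch,
                          options = transition_options(), tail_s = 60) {
  w <- protocol$epoch_windows[[epoch]]
  tail_s <- min(tail_s, protocol$break_s)
  from <- max(rec$t0, w[1] - options$prestim_s)
  to <- min(rec$t0 + length(rec$samples) / rec$sample_rate, w[2] + tail_s)
  seg <- crop_recording(rec, from, to)
  spec <- harmonic_decomposition(compute_spectrogram(seg),
                                 f0 = protocol$frequency)
  pulses <- epoch_pulses(protocol, epoch)
  pp <- power_pulsogram(seg, pulses,
                        reference_window = c(w[1], w[1] + options$baseline_s))
  markers <- detect_transitions(spec, pp, stim_window = w, options = options)
  list(markers = markers,
       label = classify_response(markers, epoch, w[2]),
       spec = spec, pp = pp)
}

#' Analyse a full multi-epoch recording
#'
#' Runs [analyze_epoch()] on every epoch and collects markers and response
#' labels.
#'
#' @inheritParams analyze_epoch
#' @return object of class `ictogenesis_summary`: `markers` (list per
#'   epoch), `labels` (character), `protocol`.
#' @export
analyze_recording <- function(rec, protocol, options = transition_options()) {
  out <- lapply(seq_len(protocol$epoch_count), function(e)
    analyze_epoch(rec, protocol, e, options = options))
  structure(
    list(markers = lapply(out, `[[`, "markers"),
         labels = vapply(out, `[[`, character(1), "label"),
         protocol = protocol),
    class = "ictogenesis_summary")
}

#' @export
print.ictogenesis_summary <- function(x, ...) {
  cat(sprintf("<ictogenesis_summary> %d epochs: %s\n",
              length(x$labels), paste(x$labels, collapse = " ")))
  for (e in seq_along(x$markers)) {
    m <- x$markers[[e]]
    fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v - m$epoch_start)
    cat(sprintf("  epoch %2d %-8s Di %s  Px %s  end %s (s from train start)\n",
                e, x$labels[e], fmt(m$divergent), fmt(m$paroxysmal),
                fmt(m$seizure_end)))
  }
  invisible(x)
}
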