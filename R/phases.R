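#' Phase markers of an epoch
#'
#' The transition points of ictogenesis for one stimulation epoch (or one
#' spontaneous seizure): the divergent point (onset of the secondary
#' discharge, start of the reverberant phase), the paroxysmal point (onset of
#' non-time-locked high-amplitude activity, the surrogate seizure onset) and
#' the seizure end point.  All times are absolute seconds on the recording
#' axis.  The behavioural point is an annotation pass-through (scored from
#' video); it is never computed by this package.
#'
#' @param epoch_start epoch (train) start time in seconds.
#' @param divergent,paroxysmal,seizure_end,behavioral transition times in
#'   seconds, `NA` when absent.
#' @return object of class `phase_markers`.
#' @export
phase_markers <- function(epoch_start, divergent = NA_real_,
                          paroxysmal = NA_real_, seizure_end = NA_real_,
                          behavioral = NA_real_) {
  m <- list(epoch_start = as.numeric(epoch_start),
            divergent = as.numeric(divergent),
            paroxysmal = as.numeric(paroxysmal),
            seizure_end = as.numeric(seizure_end),
            behavioral = as.numeric(behavioral))
  if (is.na(m$epoch_start)) stop("epoch_start is required", call. = FALSE)
  if (!is.na(m$paroxysmal) && is.na(m$divergent))
    stop("paroxysmal point requires a divergent point", call. = FALSE)
  if (!is.na(m$divergent) && m$divergent < m$epoch_start ||
      !is.na(m$paroxysmal) && m$paroxysmal <= m$divergent ||
      !is.na(m$seizure_end) && (is.na(m$paroxysmal) ||
                                m$seizure_end <= m$paroxysmal))
    stop("markers must be ordered epoch_start <= divergent < paroxysmal < seizure_end",
         call. = FALSE)
  structure(m, class = "phase_markers")
}

#' @export
print.phase_markers <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3f", v)
  cat(sprintf("<phase_markers> start %.3f | Di %s | Px %s | end %s\n",
              x$epoch_start, fmt(x$divergent), fmt(x$paroxysmal),
              fmt(x$seizure_end)))
  invisible(x)
}

#' Classify an epoch response
#'
#' Maps the detected (or ground-truth) phase markers of one epoch to the five
#' response types: `Flat` (induction phase only), `Evolving` (induction and
#' reverberant phases, no seizure), and the three seizure types -- `SzF`
#' (first seizure, epoch 1), `SzKS` (breakthrough seizure ending within 5 s
#' of stimulation end) and `SzKL` (breakthrough seizure ending beyond 5 s of
#' stimulation end).
#'
#' @param markers a [phase_markers()].
#' @param epoch_index 1-based epoch number within the recording.
#' @param stim_end stimulation (train) end time in seconds.
#' @param breakthrough_margin seconds after `stim_end` separating short from
#'   long breakthrough seizures (default 5 s).
#' @return one of `"Flat"`, `"Evolving"`, `"SzKS"`, `"SzKL"`, `"SzF"`.
#' @export
classify_response <- function(markers, epoch_index, stim_end,
                              breakthrough_margin = 5) {
  stopifnot(inherits(markers, "phase_markers"))
  if (!is.na(markers$paroxysmal) && is.na(markers$divergent))
    stop("invalid markers: paroxysmal without divergent", call. = FALSE)
  if (is.na(markers$divergent)) return("Flat")
  if (is.na(markers$paroxysmal)) return("Evolving")
  if (epoch_index == 1L) return("SzF")
  end <- markers$seizure_end
  if (!is.na(end) && end <= stim_end + breakthrough_margin) "SzKS" else "SzKL"
}

#' Interictal vs reverberant spike-rate contrast
#'
#' For spontaneous-seizure recordings: the spike rate in the reverberant
#' phase (divergent to paroxysmal point) compared with the interictal rate in
#' the 60 s window leading into the divergent point.
#'
#' @param spikes a [detect_spikes()] result (`spike_train`) or numeric spike
#'   times in seconds.
#' @param markers a [phase_markers()] with divergent and paroxysmal points.
#' @param interictal_window length of the pre-divergent window in seconds.
#' @return list with `interictal_rate`, `reverberant_rate`, `ratio`
#'   (spikes/s; `ratio` is `NA` with `undefined = TRUE` when no interictal
#'   spikes were found).
#' @export
spike_rate_contrast <- function(spikes, markers, interictal_window = 60) {
  st <- if (inherits(spikes, "spike_train")) spikes$spike_times else as.numeric(spikes)
  stopifnot(inherits(markers, "phase_markers"))
  di <- markers$divergent; px <- markers$paroxysmal
  if (is.na(di) || is.na(px))
    stop("divergent and paroxysmal markers are required", call. = FALSE)
  n_ii <- sum(st >= di - interictal_window & st < di)
  n_rv <- sum(st >= di & st < px)
  ii <- n_ii / interictal_window
  rv <- n_rv / (px - di)
  if (n_ii == 0L)
    list(interictal_rate = ii, reverberant_rate = rv, ratio = NA_real_,
         undefined = TRUE)
  else
    list(interictal_rate = ii, reverberant_rate = rv, ratio = rv / ii,
         undefined = FALSE)
}
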