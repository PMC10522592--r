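#' Optogenetic stimulation protocol
#'
#' Describes the pulse-train structure of a multi-epoch stimulation session:
#' repeated epochs, each a train of brief light pulses at a fixed frequency
#' followed by a rest break.  The canonical session is 15 epochs of a 30 s
#' train of 5 ms pulses (5, 10 or 20 Hz) with 90 s breaks.
#'
#' @param frequency pulse rate in Hz (5, 10 or 20 for the canonical protocol;
#'   any positive value is accepted).
#' @param n_epochs number of stimulation epochs.
#' @param train_s duration of each pulse train in seconds.
#' @param break_s rest between trains in seconds.
#' @param pre_s quiet baseline before the first train (and after the last)
#'   in seconds.
#' @param pulse_width light-pulse width in seconds.
#' @return object of class `stim_protocol` with fields `pulse_onsets`
#'   (seconds, strictly increasing), `pulse_width`, `frequency`,
#'   `epoch_windows` (list of `c(start, stop)` of each train), `epoch_count`,
#'   `pre_s`, `break_s` and `total_s` (recording span including baselines).
#' @examples
#' p <- stim_protocol(10, n_epochs = 2)
#' p
#' @export
stim_protocol <- function(frequency, n_epochs = 15L, train_s = 30, break_s = 90,
                          pre_s = 15, pulse_width = 0.005) {
  stop_if_not_scalar_pos(frequency, "frequency")
  stopifnot(n_epochs >= 1L, train_s > 0, break_s >= 0, pre_s >= 0,
            pulse_width > 0, pulse_width < 1 / frequency)
  starts <- pre_s + (seq_len(n_epochs) - 1L) * (train_s + break_s)
  onsets <- unlist(lapply(starts, function(s)
    s + (seq_len(floor(frequency * train_s)) - 1L) / frequency))
  structure(
    list(pulse_onsets = onsets, pulse_width = pulse_width,
         frequency = frequency,
         epoch_windows = lapply(starts, function(s) c(s, s + train_s)),
         epoch_count = as.integer(n_epochs),
         pre_s = pre_s, break_s = break_s,
         total_s = pre_s + n_epochs * (train_s + break_s) + pre_s),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d epochs of %g s at %g Hz (%g ms pulses), %g s breaks\n",
    x$epoch_count, diff(x$epoch_windows[[1]]), x$frequency,
    x$pulse_width * 1000, x$break_s))
  invisible(x)
}

# pulses belonging to epoch k (inside its train window)
epoch_pulses <- function(protocol, epoch) {
  w <- protocol$epoch_windows[[epoch]]
  protocol$pulse_onsets[protocol$pulse_onsets >= w[1] &
                          protocol$pulse_onsets < w[2]]
}

#' Write / read event tables
#'
#' Events are stored as tab-separated text with columns `onset_s`,
#' `duration_s`, `label` and `epoch`.  `write_events()` accepts either a
#' data frame with those columns or a [stim_protocol()] (each pulse becomes
#' one `"pulse"` row).  `read_events()` validates monotone onsets and
#' preserves row order, so a round trip is lossless.
#'
#' @param x data frame or `stim_protocol`.
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` returns
#'   a data frame of events.
#' @export
write_events <- function(x, path) {
  if (inherits(x, "stim_protocol")) {
    ep <- findInterval(x$pulse_onsets,
                       vapply(x$epoch_windows, `[`, numeric(1), 1L))
    x <- data.frame(onset_s = x$pulse_onsets,
                    duration_s = x$pulse_width,
                    label = "pulse", epoch = ep)
  }
  need <- c("onset_s", "duration_s", "label", "epoch")
  if (!all(need %in% names(x)))
    stop("event table must have columns onset_s, duration_s, label, epoch",
         call. = FALSE)
  write.table(x[, need], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label", "epoch")
  if (!all(need %in% names(ev)))
    stop("event table must have columns onset_s, duration_s, label, epoch",
         call. = FALSE)
  bad <- which(diff(ev$onset_s) < 0)
  if (length(bad))
    stop(sprintf("event onsets are not monotone at row %d", bad[1] + 1L),
         call. = FALSE)
  known <- c("pulse", "spike", "divergent", "paroxysmal", "seizure_end",
             "behavioral", "artifact")
  unk <- setdiff(unique(ev$label), known)
  if (length(unk))
    warning(sprintf("unknown event label(s): %s (rows kept)",
                    paste(unk, collapse = ", ")), call. = FALSE)
  ev
}

#' Rebuild a stimulation protocol from a pulse event table
#'
#' Infers the pulse frequency from the median inter-onset interval within an
#' epoch and the train windows from the first/last pulse of each epoch.
#'
#' @param events data frame from [read_events()] (rows labelled `"pulse"`).
#' @param pre_s,break_s baseline and break durations (not recoverable from
#'   the pulse rows themselves).
#' @return a [stim_protocol()].
#' @export
events_to_protocol <- function(events, pre_s = 15, break_s = 90) {
  p <- events[events$label == "pulse", , drop = FALSE]
  if (!nrow(p)) stop("no pulse events in table", call. = FALSE)
  sp <- split(p$onset_s, p$epoch)
  ioi <- median(unlist(lapply(sp, diff)))
  freq <- 1 / ioi
  train_s <- max(vapply(sp, function(o) diff(range(o)), numeric(1))) + ioi
  proto <- stim_protocol(frequency = freq, n_epochs = length(sp),
                         train_s = train_s, break_s = break_s, pre_s = pre_s,
                         pulse_width = p$duration_s[1])
  # keep the actual onsets/windows rather than the idealised grid
  proto$pulse_onsets <- p$onset_s
  proto$epoch_windows <- lapply(sp, function(o) c(o[1], o[length(o)] + ioi))
  proto
}

#' Write / read per-epoch phase markers as JSON
#'
#' Markers are keyed by epoch index; absent transitions are stored as `null`.
#'
#' @param markers list of [phase_markers()] (one per epoch).
#' @param path file path.
#' @return `write_markers()` returns `path` invisibly; `read_markers()`
#'   returns a list of `phase_markers`.
#' @export
write_markers <- function(markers, path) {
  enc <- lapply(markers, function(m) {
    m <- unclass(m)
    lapply(m, function(v) if (is.na(v)) NULL else v)
  })
  names(enc) <- as.character(seq_along(enc))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m) {
    g <- function(f) if (is.null(m[[f]])) NA_real_ else as.numeric(m[[f]])
    phase_markers(epoch_start = g("epoch_start"),
                  divergent = g("divergent"),
                  paroxysmal = g("paroxysmal"),
                  seizure_end = g("seizure_end"),
                  behavioral = g("behavioral"))
  })
}
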