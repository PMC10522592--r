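# Synthetic EEG generator: multi-epoch optogenetic stimulation sessions and
# spontaneous-seizure recordings with exported ground truth.  The generator
# is phenomenological: it reproduces the *signatures* the analysis pipeline
# keys on (pulse-locked discharge kernels, a sharp secondary-discharge onset,
# loss of pulse locking at the paroxysmal point, interictal spikes), not the
# biophysics that produces them in vivo.

#' Response specification for one stimulation epoch
#'
#' Defines the ground-truth response type of an epoch and its transition
#' times (seconds from epoch/train start).
#'
#' @param type one of `"Flat"`, `"Evolving"`, `"SzKS"`, `"SzKL"`, `"SzF"`.
#' @param divergent_time onset of the secondary discharge (required for all
#'   types except `Flat`).
#' @param paroxysmal_time onset of paroxysmal activity (seizure types only).
#' @param end_time seizure end (seizure types only).  `SzKS` must end within
#'   5 s of stimulation end, `SzKL` beyond it (checked against `train_s` at
#'   generation time).
#' @param complexity_loops number of distinct reverberant sub-patterns
#'   (secondary-discharge latency motifs).  Defaults: 0 for `Flat`, 1 for
#'   `Evolving`/`SzKS`/`SzKL`, 3 for `SzF`.
#' @return object of class `response_spec`.
#' @export
response_spec <- function(type = c("Flat", "Evolving", "SzKS", "SzKL", "SzF"),
                          divergent_time = NULL, paroxysmal_time = NULL,
                          end_time = NULL, complexity_loops = NULL) {
  type <- match.arg(type)
  is_sz <- type %in% c("SzKS", "SzKL", "SzF")
  if (type == "Flat") {
    if (!is.null(divergent_time) || !is.null(paroxysmal_time) || !is.null(end_time))
      stop("Flat responses have no transition times", call. = FALSE)
  } else {
    if (is.null(divergent_time)) stop("divergent_time is required", call. = FALSE)
    if (is_sz && (is.null(paroxysmal_time) || is.null(end_time)))
      stop("seizure specs need paroxysmal_time and end_time", call. = FALSE)
    if (!is_sz && (!is.null(paroxysmal_time) || !is.null(end_time)))
      stop("Evolving responses have no paroxysmal/end time", call. = FALSE)
  }
  tt <- c(divergent_time, paroxysmal_time, end_time)
  if (length(tt) && (any(tt <= 0) || any(diff(tt) <= 0)))
    stop("need 0 < divergent_time < paroxysmal_time < end_time", call. = FALSE)
  loops <- complexity_loops %||% switch(type, Flat = 0L, Evolving = 1L,
                                        SzKS = 1L, SzKL = 1L, SzF = 3L)
  if (loops < 0) stop("complexity_loops must be >= 0", call. = FALSE)
  structure(list(type = type,
                 divergent_time = divergent_time %||% NA_real_,
                 paroxysmal_time = paroxysmal_time %||% NA_real_,
                 end_time = end_time %||% NA_real_,
                 complexity_loops = as.integer(loops)),
            class = "response_spec")
}

#' Noise specification
#'
#' @param background_sd standard deviation of the 1/f-shaped Gaussian
#'   background, in microvolts.  The default (30 uV) is 10% of the
#'   immediate-discharge amplitude.
#' @param artifact_rate rate of transient motion-like artifacts (events/s);
#'   0 disables them (default).
#' @param seed integer RNG seed; a fixed seed yields bit-identical output.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(background_sd = 30, artifact_rate = 0, seed = 1L) {
  stop_if_not_scalar_pos(background_sd, "background_sd")
  if (artifact_rate < 0) stop("artifact_rate must be >= 0", call. = FALSE)
  structure(list(background_sd = background_sd, artifact_rate = artifact_rate,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# discharge kernel amplitudes (uV); shape choices are generator artifacts --
# the in-vivo literature constrains latency windows, not waveforms
KERNEL <- list(
  imm_amp = 300,   # immediate discharge peak
  sec_amp = 250,   # secondary discharge peak
  par_amp = 900,   # paroxysmal bursting envelope
  spike_snr = 10   # spontaneous spike peak, in units of background_sd
)

# immediate discharge: damped biphasic deflection, support [0, 10) ms
kernel_immediate <- function(fs) {
  tau <- seq(0, 0.01 - 1 / fs, by = 1 / fs)
  k <- sin(2 * pi * 100 * tau) * exp(-tau / 0.004)
  k / max(abs(k))
}

# orthonormal immediate-discharge shape basis: the induction-phase response
# evolves mostly by rotating between shapes at near-constant energy, so the
# early-band power stays flat while the response state progresses
kernel_immediate_basis <- function(fs) {
  tau <- seq(0, 0.01 - 1 / fs, by = 1 / fs)
  raw <- list(
    sin(2 * pi * 100 * tau) * exp(-tau / 0.004),
    sin(2 * pi * 70 * tau) * exp(-tau / 0.007) * sin(pi * tau / 0.01),
    sin(2 * pi * 150 * tau) * exp(-tau / 0.003) * sin(pi * tau / 0.01)^2,
    cos(2 * pi * 120 * tau) * exp(-tau / 0.005) * sin(pi * tau / 0.01))
  basis <- list()
  for (k in raw) {
    for (b in basis) k <- k - sum(k * b) * b
    basis[[length(basis) + 1L]] <- k / sqrt(sum(k^2))
  }
  scale <- 1 / max(abs(basis[[1]]))   # unit peak for the leading shape
  lapply(basis, `*`, scale)
}

# secondary discharge: slower oscillatory bump centred at `centre_ms`
# (20--50 ms support enforced by the Gaussian window and hard clipping);
# `carrier_hz` sets the discharge morphology
kernel_secondary <- function(fs, centre_ms = 30, carrier_hz = 35) {
  tau <- seq(0, 0.05 - 1 / fs, by = 1 / fs)
  c0 <- centre_ms / 1000
  k <- exp(-(tau - c0)^2 / (2 * 0.003^2)) * cos(2 * pi * carrier_hz * (tau - c0))
  k[tau < 0.02] <- 0
  k / max(abs(k))
}

# interictal spike: sharp positive-first biphasic transient, ~12 ms (wide
# enough to survive the 10 ms detection smoothing)
kernel_spike <- function(fs) {
  tau <- seq(0, 0.012 - 1 / fs, by = 1 / fs)
  k <- sin(pi * tau / 0.012)^2 * sin(2 * pi * tau / 0.012)
  k / max(k)
}

# 1/f-shaped Gaussian background, scaled to sd `sd_uv`; deterministic under
# the caller's RNG state
background_noise <- function(n, fs, sd_uv) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)            # two-sided frequency axis
  g <- 1 / sqrt(pmax(f, 1))       # 1/f power, 1 Hz floor
  x <- Re(fft(X * g, inverse = TRUE) / n)
  x * sd_uv / sd(x)
}

# amplitude-modulated 2-8 Hz bursting, frequency-drifting and phase-jittered
# relative to the pulse train; raises broad-spectrum power while breaking
# pulse locking.  `t` is time since the paroxysmal point, so with a shared
# phase motif the ictal texture of a short seizure is the initial segment of
# a longer one's (the same activity sequence unfolding further).
paroxysmal_activity <- function(t, amp, phi = runif(4, 0, 2 * pi),
                                t_abs = t) {
  dt <- if (length(t) > 1L) t[2] - t[1] else 0
  # the discharge rate glides downward over the seizure course (ictal
  # slowing), which also makes the texture progressive rather than cyclic
  finst <- pmax(3, 7 - t) + 0.3 * sin(2 * pi * 0.13 * t + phi[1])
  phase <- 2 * pi * cumsum(finst) * dt
  # the amplitude modulation rides on the epoch clock (an ongoing network
  # oscillation), not on seizure age
  env <- 0.65 + 0.35 * sin(2 * pi * 0.9 * t_abs + phi[2])
  # the discharge waveform morphs rapidly over the first seconds (harmonic
  # content shifts) and then settles into a sustained clonic pattern: a
  # longer seizure continues the same steady ictal state
  a2 <- pmax(0.14, 0.5 - 0.09 * t)
  a3 <- pmin(0.47, 0.15 + 0.08 * t)
  x <- sin(phase + phi[3]) + a2 * sin(2 * phase + phi[4]) +
    a3 * sin(3 * phase + phi[1])
  amp * env * x / max(abs(x))
}

#' Per-recording response motif
#'
#' Random phases defining the slow immediate-discharge drift and the ictal
#' bursting texture.  Epochs of one recording share a motif: the same
#' response circuit is traversed progressively by all response types of a
#' session, so flat responses, evolving responses and seizures from one
#' recording are successive extensions of one underlying activity sequence.
#'
#' @return list with `drift_phi` (2 phases) and `par_phi` (4 phases).
#' @export
response_motif <- function() {
  list(drift_phi = runif(2, 0, 2 * pi), par_phi = runif(4, 0, 2 * pi))
}

# Secondary-discharge latency (ms) as a function of reverberant fraction w.
# One loop sweeps 24 -> 38 ms; multiple loops split the 24--44 ms range into
# disjoint bands swept one after another in a shuffled fixed order, so each
# loop is a distinct sub-pattern and the jumps between bands are sharp
# direction changes of the response trajectory.
loop_latency <- function(w, L) {
  if (L <= 1L) return(list(lat = 26 + 10 * w, carrier = 35))
  order <- c(2L, 1L, seq_len(L)[-(1:2)])        # start mid-band, then low
  j <- min(L, 1L + floor(w * L))
  w_loc <- w * L - (j - 1L)
  band <- order[j]
  lo <- 26 + 20 * (band - 1L) / L
  hi <- 26 + 20 * (band - 0.35) / L
  # each loop also has its own discharge morphology (carrier frequency):
  # distinct reverberant sub-patterns, not just shifted copies
  list(lat = lo + (hi - lo) * w_loc,
       carrier = c(35, 55, 25, 45, 65)[1L + (band - 1L) %% 5L])
}

#' Generate the evoked response of a single epoch
#'
#' Builds the noiseless pulse-locked response for one stimulation train:
#' an immediate-discharge kernel 0--10 ms after every pulse; from the
#' divergent point on, a secondary-discharge kernel 20--50 ms after each
#' pulse whose amplitude ramps up over `ramp_s`; from the paroxysmal point to
#' `end_time`, high-amplitude bursting not phase-locked to the pulses
#' replaces the time-locked components.  When `complexity_loops > 1` the
#' secondary-discharge latency switches between `complexity_loops` motifs
#' across the reverberant phase.
#'
#' @param spec a [response_spec()].
#' @param pulse_times pulse onsets in seconds from epoch start (strictly
#'   increasing).
#' @param fs sample rate in Hz.
#' @param duration_s epoch span to synthesise, seconds from train start.
#' @param stim_s train duration in seconds (transition-time validity checks).
#' @param ramp_s rise time of the secondary discharge after the divergent
#'   point.
#' @param drift if `TRUE` (default) the immediate-discharge amplitude drifts
#'   smoothly (~25%) over the train, emulating the slow shape evolution of
#'   real induction-phase responses; `FALSE` gives a strictly repeating
#'   kernel (every pulse-aligned strip identical in the absence of noise).
#' @param motif a [response_motif()]; epochs of one recording should share
#'   one motif.  `NULL` draws a fresh motif from the caller's RNG state.
#' @return numeric vector of `duration_s * fs` voltage samples (uV), noise
#'   free; time 0 is the train start.
#' @export
synth_epoch_response <- function(spec, pulse_times, fs = 3000,
                                 duration_s = 60, stim_s = 30, ramp_s = 1,
                                 drift = TRUE, motif = NULL) {
  stopifnot(inherits(spec, "response_spec"))
  if (length(pulse_times) && any(diff(pulse_times) <= 0))
    stop("pulse_times must be strictly increasing", call. = FALSE)
  is_sz <- spec$type %in% c("SzKS", "SzKL", "SzF")
  if (!is.na(spec$divergent_time) && is_sz && spec$divergent_time >= stim_s)
    stop("divergent_time must precede stimulation end for seizure specs",
         call. = FALSE)
  n <- round(duration_s * fs)
  x <- numeric(n)
  kp <- kernel_immediate_basis(fs)
  if (is.null(motif)) motif <- response_motif()
  drift_phi <- motif$drift_phi
  # Progression through the underlying activity sequence is indexed by phase
  # fraction, not wall-clock time: a response that diverges early traverses
  # the induction content quickly, a flat response spreads it over the whole
  # train.  This realises the successive nesting of response types -- a
  # lower-order response is the same sequence traversed more slowly and
  # truncated earlier.
  t_ind <- if (!is.na(spec$divergent_time)) spec$divergent_time else stim_s
  di <- spec$divergent_time
  px <- spec$paroxysmal_time
  se <- spec$end_time
  rev_end <- if (!is.na(px)) px else stim_s
  L <- max(spec$complexity_loops, 1L)
  for (tp in pulse_times) {
    if (!is.na(px) && tp >= px) next        # paroxysmal activity takes over
    i0 <- round(tp * fs) + 1L
    u <- min(tp / t_ind, 1)                 # induction content fraction
    # the dominant shape coordinate grows monotonically in u, keeping the
    # content curve injective (the response only progresses, it never
    # revisits an earlier state); a smaller orthogonal-shape wiggle gives
    # the evolution a second dimension
    k_imm <- if (drift) {
      # constant-speed rotation in the (3rd, 4th) shape plane: the shape
      # evolution never stalls, so the state is identifiable at any u
      KERNEL$imm_amp *
        ((0.9 + 0.25 * u) * kp[[1]] +
           0.35 * (1 - 0.85 * u^6) *
             (sin(2 * pi * 4 * u + drift_phi[1]) * kp[[3]] +
                cos(2 * pi * 4 * u + drift_phi[1]) * kp[[4]]))
    } else KERNEL$imm_amp * kp[[1]]
    idx <- i0:(i0 + length(k_imm) - 1L)
    ok <- idx <= n
    x[idx[ok]] <- x[idx[ok]] + k_imm[ok]
    if (!is.na(di) && tp >= di && spec$complexity_loops >= 1L) {
      ramp <- min(1, (tp - di) / ramp_s)
      w <- min(1, (tp - di) / max(rev_end - di, 1e-9))  # reverberant fraction
      lp <- loop_latency(w, L)
      ks <- kernel_secondary(fs, lp$lat, lp$carrier) * KERNEL$sec_amp
      idx <- i0:(i0 + length(ks) - 1L)
      ok <- idx <= n
      x[idx[ok]] <- x[idx[ok]] + ramp * ks[ok]
    }
  }
  if (!is.na(px)) {
    stop_t <- min(se, duration_s, na.rm = TRUE)
    i0 <- round(px * fs) + 1L
    i1 <- min(n, round(stop_t * fs))
    if (i1 > i0) {
      tt <- (i0:i1 - 1L) / fs
      # ictal texture indexed by time since the paroxysmal point: a short
      # seizure's ictal sequence is the initial segment of a longer one's
      burst <- paroxysmal_activity(tt - px, KERNEL$par_amp, motif$par_phi,
                                   t_abs = tt)
      onset <- pmin(1, (tt - px) / 0.3)     # 300 ms onset ramp
      offset <- pmin(1, pmax(0, (stop_t - tt) / 0.3))
      x[i0:i1] <- x[i0:i1] + burst * onset * offset
    }
  }
  x
}

#' Generate a synthetic multi-epoch optogenetic recording
#'
#' Assembles a full stimulation session: 1/f background noise spanning all
#' epochs plus pre/post baselines, with each epoch's evoked response given by
#' its [response_spec()].  Ground truth equals the schedule.
#'
#' @param protocol a [stim_protocol()].
#' @param schedule list of [response_spec()], one per epoch.  `SzF` is only
#'   allowed at epoch 1 (first seizures occur in the first train of a
#'   session).
#' @param noise a [noise_spec()].
#' @param fs sample rate in Hz (3 kHz matches the acquisition emulated here).
#' @return list with `recording` ([eeg_recording()]), `markers` (list of
#'   ground-truth [phase_markers()] per epoch, absolute seconds) and `labels`
#'   (character vector of response types).
#' @examples
#' p <- stim_protocol(10, n_epochs = 2, train_s = 8, break_s = 4, pre_s = 3)
#' sched <- list(response_spec("Flat"),
#'               response_spec("Evolving", divergent_time = 4))
#' out <- synth_optogenetic_recording(p, sched, noise_spec(seed = 7))
#' out$labels
#' @export
synth_optogenetic_recording <- function(protocol, schedule,
                                        noise = noise_spec(), fs = 3000) {
  stopifnot(inherits(protocol, "stim_protocol"), inherits(noise, "noise_spec"))
  if (length(schedule) != protocol$epoch_count)
    stop("schedule length must equal the epoch count", call. = FALSE)
  lab <- vapply(schedule, function(s) s$type, character(1))
  if (any(lab[-1] == "SzF"))
    stop("SzF (first seizure) is only allowed at epoch 1", call. = FALSE)
  ws <- vapply(protocol$epoch_windows, `[`, numeric(1), 1L)
  if (protocol$epoch_count > 1L &&
      any(diff(ws) < diff(protocol$epoch_windows[[1]])))
    stop("epoch windows overlap", call. = FALSE)
  train_s <- diff(protocol$epoch_windows[[1]])
  span_s <- train_s + protocol$break_s
  n <- round(protocol$total_s * fs)
  set.seed(noise$seed)
  x <- background_noise(n, fs, noise$background_sd)
  motif <- response_motif()   # one activity motif per recording
  markers <- vector("list", protocol$epoch_count)
  for (e in seq_len(protocol$epoch_count)) {
    spec <- schedule[[e]]
    w <- protocol$epoch_windows[[e]]
    pt <- epoch_pulses(protocol, e) - w[1]
    dur <- min(span_s, protocol$total_s - w[1])
    resp <- synth_epoch_response(spec, pt, fs = fs, duration_s = dur,
                                 stim_s = train_s, motif = motif)
    i0 <- round(w[1] * fs) + 1L
    idx <- i0:(i0 + length(resp) - 1L)
    ok <- idx <= n
    x[idx[ok]] <- x[idx[ok]] + resp[ok]
    markers[[e]] <- phase_markers(
      epoch_start = w[1],
      divergent = w[1] + spec$divergent_time,
      paroxysmal = w[1] + spec$paroxysmal_time,
      seizure_end = w[1] + spec$end_time)
  }
  if (noise$artifact_rate > 0) {
    n_art <- rpois(1, noise$artifact_rate * protocol$total_s)
    if (n_art > 0) {
      at <- runif(n_art, 0, protocol$total_s - 0.2)
      for (a in at) {
        i0 <- round(a * fs) + 1L
        tau <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
        bump <- 8 * noise$background_sd * sin(pi * tau / 0.2)^2
        idx <- i0:(i0 + length(bump) - 1L)
        ok <- idx <= n
        x[idx[ok]] <- x[idx[ok]] + bump[ok]
      }
    }
  }
  list(recording = eeg_recording(x, fs, t0 = 0, channel_name = "synthCA1"),
       markers = markers, labels = lab)
}

#' Generate a synthetic spontaneous-seizure recording
#'
#' Emulates a chronic-epilepsy recording: interictal spikes at a baseline
#' rate; for each scheduled seizure, spiking accelerates to
#' `reverberant_rate` between the divergent and paroxysmal points with each
#' spike carrying an added secondary component 15--50 ms after its peak;
#' continuous ictal bursting between the paroxysmal point and seizure end.
#'
#' @param duration_s recording length in seconds.
#' @param interictal_rate baseline spike rate (spikes/s, > 0).
#' @param seizure_specs list of numeric `c(divergent, paroxysmal, end)` times
#'   in seconds; windows must not overlap.
#' @param reverberant_rate spike rate in the reverberant phase (spikes/s,
#'   must exceed `interictal_rate`).
#' @param noise a [noise_spec()]; spike amplitude is
#'   `10 * background_sd`.
#' @param fs sample rate in Hz.
#' @return list with `recording`, `spike_times` (ground truth, seconds) and
#'   `markers` (list of [phase_markers()] per seizure).
#' @export
synth_spontaneous_recording <- function(duration_s, interictal_rate = 0.5,
                                        seizure_specs = list(),
                                        reverberant_rate = 5,
                                        noise = noise_spec(), fs = 3000) {
  if (interictal_rate <= 0 || reverberant_rate <= 0)
    stop("rates must be > 0", call. = FALSE)
  if (reverberant_rate <= interictal_rate)
    stop("reverberant_rate must exceed interictal_rate", call. = FALSE)
  if (length(seizure_specs) > 1L) {
    m <- do.call(rbind, seizure_specs)
    if (any(m[-1, 1] < m[-nrow(m), 3]))
      stop("seizure windows overlap", call. = FALSE)
  }
  for (s in seizure_specs)
    if (length(s) != 3L || any(diff(s) <= 0) || s[1] <= 0 || s[3] > duration_s)
      stop("each seizure spec must be increasing c(divergent, paroxysmal, end) within the recording",
           call. = FALSE)
  set.seed(noise$seed)
  n <- round(duration_s * fs)
  x <- background_noise(n, fs, noise$background_sd)
  # piecewise spike process: exponential gaps with a 50 ms dead time,
  # compensated so the mean rate equals the nominal rate
  gap <- function(rate) {
    dead <- 0.05
    if (1 / rate <= dead) stop("rate too high for the 50 ms dead time")
    dead + rexp(1, 1 / (1 / rate - dead))
  }
  in_phase <- function(t, col) {
    for (s in seizure_specs) if (t >= s[1] && t < s[2]) return(TRUE)
    FALSE
  }
  in_ictal <- function(t) {
    for (s in seizure_specs) if (t >= s[2] && t < s[3]) return(TRUE)
    FALSE
  }
  rate_at <- function(t) if (in_phase(t)) reverberant_rate else interictal_rate
  # boundaries where the rate changes (divergent / paroxysmal points)
  bounds <- sort(unlist(lapply(seizure_specs, function(s) s[1:2])))
  spike_times <- numeric(0)
  t <- gap(interictal_rate)
  while (t < duration_s) {
    if (in_ictal(t)) {
      # jump past the ictal window; no discrete spikes during the seizure
      for (s in seizure_specs) if (t >= s[2] && t < s[3]) t <- s[3]
      t <- t + gap(interictal_rate)
      next
    }
    spike_times <- c(spike_times, t)
    r0 <- rate_at(t)
    t1 <- t + gap(r0)
    # memoryless rescaling of the residual waiting time at rate boundaries
    repeat {
      b <- bounds[bounds > t & bounds < t1]
      if (!length(b)) break
      b <- b[1]
      r1 <- rate_at(b)
      if (r1 == r0) { t <- b; next }
      t1 <- b + (t1 - b) * r0 / r1
      t <- b
      r0 <- r1
    }
    t <- t1
  }
  amp <- KERNEL$spike_snr * noise$background_sd
  k_sp <- kernel_spike(fs) * amp
  # reverberant-phase secondary component: support 15--50 ms after the
  # peak.  Negative-going, so it carries late-band power without
  # registering as a separate positive discharge in the detector.
  k_sec2 <- kernel_secondary(fs, 28)
  k_sec2[seq_len(round(0.015 * fs))] <- 0
  k_sec2 <- -abs(k_sec2) * 0.8 * amp
  peak_off <- which.max(kernel_spike(fs)) - 1L
  for (ts in spike_times) {
    i0 <- round(ts * fs) + 1L
    idx <- i0:(i0 + length(k_sp) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + k_sp[ok]
    if (in_phase(ts)) {
      idx <- (i0 + peak_off):(i0 + peak_off + length(k_sec2) - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + k_sec2[ok]
    }
  }
  for (s in seizure_specs) {
    i0 <- round(s[2] * fs) + 1L
    i1 <- min(n, round(s[3] * fs))
    tt <- (i0:i1 - 1L) / fs
    burst <- paroxysmal_activity(tt - s[2], 1.5 * amp)
    onset <- pmin(1, (tt - s[2]) / 0.3)
    offset <- pmin(1, pmax(0, (s[3] - tt) / 0.3))
    x[i0:i1] <- x[i0:i1] + burst * onset * offset
  }
  markers <- lapply(seizure_specs, function(s)
    phase_markers(epoch_start = max(0, s[1] - 60), divergent = s[1],
                  paroxysmal = s[2], seizure_end = s[3]))
  list(recording = eeg_recording(x, fs, t0 = 0, channel_name = "synthKA"),
       spike_times = spike_times, markers = markers)
}
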