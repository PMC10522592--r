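---
title: "Pulsograms and the phases of ictogenesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulsograms and the phases of ictogenesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsogram)
```

## The problem this package addresses

When hippocampal CA1 excitatory neurons are driven with trains of brief
light pulses (5 ms pulses at 5--20 Hz for 30 s, repeated every 2 minutes),
the local field potential response sometimes stays a stereotyped evoked
response and sometimes escalates into a full electrographic seizure.  The
transition -- ictogenesis -- is not gradual: it proceeds through discrete
phases separated by sharp transition points.

* **Induction phase**: every light pulse evokes an *immediate discharge*,
  a stereotyped deflection confined to the first ~10 ms after the pulse.
* **Divergent point (Di)**: a *secondary discharge* appears, time-locked
  20--50 ms after each pulse, marking the start of the **reverberant
  phase**.  Its onset is abrupt, visible as a sharp rise of late-band
  (20--50 ms) post-pulse power.
* **Paroxysmal point (Px)**: pulse locking breaks down and high-amplitude
  activity unsynchronised to the stimulus takes over -- the surrogate for
  electrographic seizure onset, visible in the spectrogram as a sudden
  loss of the stimulation-frequency harmonics together with a broad power
  rise.

Epoch responses fall into five classes: `Flat` (induction only),
`Evolving` (induction + reverberant), and three seizure types -- the first
seizure of a session (`SzF`, epoch 1), and breakthrough seizures ending
within (`SzKS`) or beyond (`SzKL`) 5 s of stimulation end.

The package's central data structure is the **pulsogram**: snippets of the
EEG locked to each stimulus pulse (or, for spontaneous seizures, to each
detected interictal spike), stacked in chronological order into a
pulse-time x train-time matrix.  All downstream analyses -- instantaneous
power maps, transition detection, and trajectory analysis -- operate on
this representation.

## The processing model

### Pulsogram and power pulsogram

`build_pulsogram()` slices -5..60 ms around each anchor; the strips are
exact re-slices of the raw trace (no smoothing), so the pulsogram is
loss-free.  For pulse anchors the grid can be extrapolated at the pulse
period beyond each train (`extrapolate_s`).

`power_pulsogram()` replaces voltage by instantaneous power: the squared
Hilbert envelope, smoothed with a 10 ms 2nd-order Savitzky--Golay filter,
sliced the same way, and expressed in dB relative to a per-pulse-time
reference.  The reference is the arithmetic mean of linear power over the
reference strips (the induction phase, or for spike-anchored pulsograms
the 60 s leading into the divergent point), computed row by row -- so the
reference region averages to the 0 dB level *in linear power* at every
pulse time.  Note that the mean of the *dB values* over the reference can
sit below 0 dB whenever row power fluctuates strongly (Jensen's
inequality); for that reason `delta_power()` averages band power in the
linear domain (the area under the power curve over the band) and converts
the ratio to dB at the end.

### Trajectory preprocessing

Before trajectory analysis the pulsogram passes three stages, in order:

1. smoothing along pulse time (2 ms, 2nd-order Savitzky--Golay);
2. per-strip normalisation by `kappa[x] = sqrt((v[x] + v0) / 2)`, with
   `v[x]` the strip power over -5..50 ms and `v0` the mean of `v` over
   stimulation strips.  This is a regularised scale: a silent strip is
   divided by `sqrt(v0/2)` rather than blowing up, and a strip with 100x
   the mean power retains only about twice the mean power -- spurious
   high-power strips (artifacts, overwhelming ictal activity) are
   attenuated boundedly;
3. smoothing along train time (2 s, 2nd-order Savitzky--Golay).

Savitzky--Golay filters use polynomial-fit edges (no reflection padding),
and the train-time smoothing is applied within contiguous anchor blocks
only, so content never bleeds across the inter-train breaks.  The output
is cropped to -5..50 ms and treated as an n-dimensional trajectory with
one point per strip.

### Transition detection

`detect_transitions()` operationalises the phase signatures:

* **divergent**: the mean late-band (20--50 ms) dB of stimulation strips,
  lightly smoothed over 0.5 s of strips, must exceed the mean + 3 SD of
  the first 2 s of stimulation, sustained over 1 s of strips (a window
  counts as sustained when at least 90% of its strips qualify, so an
  isolated noisy strip does not reset the detector).  The onset is then
  refined backwards with a mean + 1 SD hysteresis threshold, because the
  certifying threshold is crossed a fraction of a second after the true
  onset of the amplitude ramp.
* **paroxysmal**: the harmonic fraction of the spectrogram (power in
  `k f0 +- 1 Hz` bands up to 200 Hz over total 0--200 Hz power) must fall
  below 50% of its causal 5 s running median while total power (smoothed
  over 1 s, so amplitude-modulated bursting does not dip below criterion)
  exceeds the pre-stimulation baseline mean + 3 SD, sustained 0.5 s.
* **seizure end**: total power returns below baseline + 2 SD for 2 s.

All thresholds are operational choices exposed in
`transition_options()`; they are anchored to the qualitative spectral
signatures, not to measured quantities.  A paroxysmal candidate without a
preceding divergent point is discarded, so emitted markers always satisfy
`start <= Di < Px < end`.

The spectrogram itself uses the acquisition-matched 0.33 s Hann window
with 87.5% overlap, scaled as a one-sided PSD so that band-integrated
power matches time-domain variance.  The FFT is zero-padded to a 1 Hz
frequency grid: harmonics of integer stimulation frequencies then sit on
bin centres and the +-1 Hz harmonic bands are meaningful at any window
length.  With a 0.33 s window the Hann main lobe is ~6 Hz wide, so even a
pure tone leaves a substantial fraction of its energy outside a +-1 Hz
band; absolute harmonic fractions therefore depend on the window, while
the detector keys only on the *relative* collapse of the fraction.  (The
energy-capture checks in the test suite use a 1 s window, where a
resolved integer-frequency tone falls entirely inside its band.)

### Trajectory analyses

* `pca_embed()` -- PCA over strips (mean-centred, no variance scaling
  since strips share units after the kappa normalisation); the latent
  dimensionality summary `n_components_90` is the number of components
  needed for 90% of variance.
* `dtw_compare()` -- dynamic time warping with the classic symmetric step
  set and per-point Euclidean cost, computed exactly by dynamic
  programming (verified against an independent oracle in the tests).  The
  *coverage curve* expresses nesting: for each fraction of the
  higher-order trajectory consumed, the largest fraction of the
  lower-order trajectory already matched (a single-valued % vs % curve).
  If response A is a sub-segment of the content of response B, A's curve
  lies on or above the diagonal.  Both directions are reported.
  `normalize_distances()` divides raw separation distances by the mean
  distance from the epoch-1 trajectory to all other epochs of the same
  recording.
* `angular_segmentation()` -- at each point, the angle between the
  displacement from the 1 s-mean before the point and the displacement to
  the 1 s-mean after it; the reported turning angle is 180 degrees minus
  that included angle, so a straight course scores ~180 and a sharp
  direction reversal scores near 0.  Segmentation points are troughs
  below 90 degrees with at least 30 degrees prominence, retained only if
  separated by more than 0.67 s, displaced by more than `d / sqrt(2)`
  (with `d` the mean inter-point step) in adjacent segment means, and
  with adjacent segment-mean correlation below 0.9.  The correlation
  guard is what keeps a noisy-but-straight trajectory in one piece; when
  a segment mean is constant the correlation is treated as 0 (retention
  allowed) since the guard is undefined there.
* `rdp_segmentation()` -- Ramer--Douglas--Peucker simplification in the
  full n-dimensional space.  The default tolerance is twice the mean step
  of the trajectory passed in; for comparing complexity *across* epochs
  of one recording, pass a common `epsilon` (the batch analyses use twice
  the mean step of the full-recording trajectory) so that all epochs are
  measured against the same yardstick.

### Response classification and spike analysis

`classify_response()` maps markers to the five classes; the breakthrough
short/long boundary is `stim_end + 5 s` (a seizure ending exactly at the
boundary is break-short).  `detect_spikes()` finds positive-going
discharges above 6 unscaled median absolute deviations about zero
(matching the spike-anchored pulsogram convention; the MAD is *not*
scaled by 1.4826 and is computed about zero, not about the median), on a
10 ms Savitzky--Golay smoothed trace, discarding any peak closer than
20 ms to the previously retained one so that only the first peak of a
multi-phasic discharge remains.  `spike_rate_contrast()` compares the
reverberant-phase spike rate against the 60 s interictal window before
the divergent point.

## The synthetic-data generator

No raw in-vivo recording ships with the package; every pipeline stage is
exercised against `synth_optogenetic_recording()` and
`synth_spontaneous_recording()`, which emulate the study conditions:
15-epoch sessions of 30 s trains (5 ms pulses, 5/10/20 Hz) with 90 s
breaks at 3 kHz, and long-term recordings with interictal spikes.

The generator is phenomenological.  What it emulates, and how:

* **Immediate discharge**: a damped biphasic kernel confined to 0--10 ms
  after each pulse.  Its shape *evolves* over the induction phase -- the
  dominant shape coordinate grows monotonically while a smaller
  orthogonal-shape component rotates at constant speed -- because real
  induction responses visibly drift in shape.  Monotone progression makes
  the response state curve injective (the response never revisits an
  earlier state), which is what lets time warping align two responses
  unambiguously; the constant-speed rotation keeps the state identifiable
  at every moment.  The evolution is energy-preserving up to a ~25%
  amplitude trend capped at the divergent point, keeping early-band
  (0--20 ms) power approximately stable between phases, as observed.
* **Progression is indexed by phase fraction, not wall time.**  A flat
  response traverses the induction content over its whole train; a
  response that diverges after 5 s traverses the same content in 5 s.
  This realises, mechanistically, the successive nesting of response
  types: a lower-order response is the same activity sequence traversed
  more slowly and truncated earlier.  Epochs of one recording share a
  random "motif" (drift and bursting phases), reflecting that one
  session's responses traverse one underlying circuit.
* **Secondary discharge**: an oscillatory bump with 3 ms Gaussian
  envelope whose latency sweeps 26 to 36 ms across the reverberant phase,
  with amplitude ramping over 1 s after the divergent point (the sharp
  onset the detector keys on).  With `complexity_loops >= 2` the latency
  range splits into disjoint bands visited in a shuffled order and each
  band carries its own carrier frequency: each loop is a *distinct*
  reverberant sub-pattern, so first seizures (more loops) produce more
  angular segments and more latent dimensions downstream.
* **Paroxysmal activity**: amplitude-modulated bursting whose discharge
  rate glides from ~7 Hz down to 3 Hz over the first seconds (ictal
  slowing) while the waveform's harmonic content morphs and then settles
  into a sustained clonic pattern; the amplitude modulation rides on the
  epoch clock rather than on seizure age.  The activity is not locked to
  the pulse train, replaces the time-locked kernels, and raises
  broad-spectrum power, so the harmonic fraction collapses at the
  paroxysmal point.  A short seizure's ictal sequence is the initial
  segment of a longer one's.
* **Background**: 1/f-shaped Gaussian noise with default SD 30 uV -- 10%
  of the 300 uV immediate-discharge amplitude.  Optional transient
  artifacts are off by default.
* **Spontaneous recordings**: interictal spikes (12 ms positive-first
  biphasic transients at 10x the background SD) drawn from a dead-time
  Poisson process whose rate switches at the divergent point
  (memorylessly, so the first reverberant spikes are not delayed by a
  long preceding interictal gap); reverberant spikes carry an added
  negative-going 15--50 ms secondary component strong in power but
  invisible to the positive-peak detector; continuous ictal bursting
  between the paroxysmal point and seizure end.

**What the generator does not emulate** -- and hence what passing tests
do and do not show: there is no biophysical network, no electrode drift
or impedance change, no movement artifact by default, no behavioural
correlate, and the noiseless content curves are far cleaner than real
LFPs.  Passing the recovery and ordering suites shows the *pipeline* is
correct and consistent with the intended signatures; it is not evidence
about detection performance on real recordings, where the spontaneous
divergent/paroxysmal points in particular were identified by visual
inspection in the original work.

### Study-condition defaults used by the test batteries

The multi-epoch batch used by the trajectory test suites holds all five
response types per recording, with transition times (seconds from train
start, jittered +-0.5 s): `SzF` Di 5, Px 20, end 40, 5 loops (first
seizures have the shortest induction and the most complex reverberance);
`Evolving` Di 17; `SzKS` Di 14, Px 26, end 34; `SzKL` Di 7, Px 18,
end 45.  Breakthrough inductions are longer than first-seizure
inductions, and the break-short/break-long end times sit on either side
of the 5 s boundary.  Batch sizes follow the property suites (50
recordings for the nesting/complexity properties, 100 single epochs for
transition recovery); at 3 kHz these run in a few minutes on one CPU.

## Numerical choices and degenerate inputs

* Savitzky--Golay windows are converted to the nearest odd sample count;
  series shorter than the window fall back to the largest feasible odd
  window.
* The divergent detector's baseline is the first 2 s of stimulation
  strips; epochs shorter than the baseline are an error.
* An all-zero recording has zero MAD and `detect_spikes()` refuses it
  rather than dividing by zero; `preprocess_trajectory()` refuses a
  recording whose mean strip power `v0` is zero.
* DTW distance between identical trajectories is 0 up to floating-point
  rounding of the cross-distance matrix (~1e-8 on typical magnitudes).
* The EDF writer requires integer sample rates, pads the final 1 s data
  record with zeros, and records the true sample count in the reserved
  header field so a round trip preserves length; amplitudes quantise to
  16 bits of the declared physical range (+-5000 uV by default).
* Event-aligned rescaling uses piecewise-linear monotone warps with 100
  grid points per segment; traces missing a boundary marker are excluded
  with a message.

## The optics utility

`activation_depth()` computes how deep below the fibre tip 465 nm light
stays above the channelrhodopsin activation threshold, combining on-axis
conical spread (half angle `asin(NA/n)`, characteristic distance
`rho = r * sqrt((n/NA)^2 - 1)`) with Kubelka--Munk scattering
`1/(S z + 1)`; the default scattering coefficient is 11.2 /mm (mouse
grey matter, ~473 nm).  The canonical worked example takes 1.46 mW at
the cannula tip, NA 0.57, the printed 400 um figure read as the core
radius, n = 1.35 and a 1 mW/mm^2 threshold:

```{r optics}
fib <- fiber_spec(1.46, 0.57, 0.4)
activation_depth(fib)
```

Two ambiguities deserve note.  First, "400 um" may denote the core
diameter (radius 0.2 mm) rather than the radius; both conventions are one
argument away (`core_radius_mm = 0.2` gives a substantially larger
depth, since the same power starts at 4x the surface irradiance over a
narrower cone).  Second, with the cannula-tip power of 1.46 mW this model
yields ~0.11 mm, whereas the frequently quoted ~0.15 mm figure is
recovered only with the ~1.9--2.0 mW power measured at the patch-cord
tip.  The function reports whatever follows from the parameters it is
given; the acceptance script uses the cannula-tip reading.

## Known limitations

* The transition detectors are tuned to the synthetic signatures; on real
  data the thresholds in `transition_options()` will need adjustment, and
  spontaneous-seizure markers remain an extrapolation validated only on
  synthetic ground truth.
* DTW nesting is assessed per instance against a strict
  on-or-above-the-diagonal criterion; at realistic noise the warping path
  can undershoot the diagonal by a strip or two near its constrained
  terminus, so a small fraction of instances fail even under genuinely
  nested content.
* The spike detector is positive-going only, and artifact rejection
  beyond the kappa regularisation is out of scope.
* Group-level inferential statistics (ANOVAs, rank tests across animals)
  are deliberately not implemented.
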