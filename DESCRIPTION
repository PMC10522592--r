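Package: pulsogram
Title: Pulse-Locked EEG Pulsograms and the Phases of Ictogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the transition from interictal activity to
    seizures (ictogenesis) in single-channel hippocampal EEG/LFP recordings.
    Builds time-vs-time "pulsograms" of snippets locked to optogenetic
    stimulation pulses or to detected interictal spikes, computes Hilbert
    instantaneous-power pulsograms, decomposes spectrograms into
    stimulation-harmonic and non-harmonic power, detects the divergent and
    paroxysmal transition points that demarcate the induction, reverberant
    and paroxysmal phases, classifies epoch responses, and quantifies
    response nesting and complexity with PCA, dynamic time warping and
    angular / Ramer-Douglas-Peucker trajectory segmentation.  Includes a
    synthetic EEG generator emulating multi-epoch optogenetic stimulation
    sessions and spontaneous-seizure recordings with ground-truth markers,
    simple EDF and event-table input/output, and a fibre-optic
    light-activation depth calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
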