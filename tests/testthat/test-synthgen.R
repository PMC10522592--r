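test_that("protocol pulse bookkeeping matches the stated paradigm", {
  p <- stim_protocol(10, n_epochs = 15)
  expect_equal(length(p$pulse_onsets), 15L * 300L)  # 10 Hz x 30 s per train
  expect_true(all(diff(p$pulse_onsets) > 0))
  expect_gte(p$total_s, 1800)
  out <- synth_optogenetic_recording(
    stim_protocol(10, n_epochs = 2, train_s = 5, break_s = 5, pre_s = 2),
    list(response_spec("Flat"), response_spec("Flat")), noise_spec(seed = 1))
  expect_equal(length(out$recording$samples) / 3000,
               2 + 2 * 10 + 2, tolerance = 1e-9)
})

test_that("identical noise seeds give bit-identical recordings", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 5, break_s = 2, pre_s = 2)
  sched <- list(response_spec("SzKL", 1.5, 3, 6))
  a <- synth_optogenetic_recording(p, sched, noise_spec(seed = 42))
  b <- synth_optogenetic_recording(p, sched, noise_spec(seed = 42))
  expect_identical(a$recording$samples, b$recording$samples)
  c <- synth_optogenetic_recording(p, sched, noise_spec(seed = 43))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("schedule validation rejects malformed sessions", {
  p <- stim_protocol(10, n_epochs = 2, train_s = 5, break_s = 2, pre_s = 1)
  expect_error(synth_optogenetic_recording(
    p, list(response_spec("Flat"),
            response_spec("SzF", 1, 2, 4)), noise_spec(seed = 1)),
    "epoch 1")
  expect_error(synth_optogenetic_recording(
    p, list(response_spec("Flat")), noise_spec(seed = 1)), "schedule length")
  expect_error(response_spec("SzKS", 5, 4, 10))       # px before divergent
  expect_error(response_spec("Flat", divergent_time = 3))
  expect_error(response_spec("Evolving"))
  expect_error(noise_spec(background_sd = 0))
})

test_that("a Flat epoch adds no late-band energy and carries no markers", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 10, break_s = 2, pre_s = 3)
  out <- synth_optogenetic_recording(p, list(response_spec("Flat")),
                                     noise_spec(seed = 3))
  m <- out$markers[[1]]
  expect_true(is.na(m$divergent) && is.na(m$paroxysmal))
  # 20-50 ms post-pulse band power ~ pre-stimulation power
  pg <- build_pulsogram(out$recording, p)
  rows <- pg$y_ms >= 20 & pg$y_ms < 50
  band <- mean(pg$values[rows, ]^2)
  pre <- mean(out$recording$samples[1:(3 * 3000)]^2)
  expect_lt(abs(10 * log10(band / pre)), 1.5)
})

test_that("the divergent point doubles late-band power in an Evolving epoch", {
  pulse_times <- seq(0, 29.9, by = 0.1)
  set.seed(1)
  x <- synth_epoch_response(response_spec("Evolving", 12), pulse_times,
                            fs = 3000, duration_s = 30)
  rec <- eeg_recording(x + 1e-9, 3000)
  pg <- build_pulsogram(rec, pulse_times[2:295])
  rows <- pg$y_ms >= 20 & pg$y_ms < 50
  bp <- colMeans(pg$values[rows, ]^2)
  late <- mean(bp[pg$anchor_times > 13])
  early <- mean(bp[pg$anchor_times < 12])
  expect_gt(late / early, 2)
})

test_that("paroxysmal activity breaks pulse locking", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 30, break_s = 10, pre_s = 5)
  out <- synth_optogenetic_recording(p, list(response_spec("SzKS", 10, 20, 33)),
                                     noise_spec(seed = 3))
  pg <- build_pulsogram(out$recording, p)
  w <- p$epoch_windows[[1]]
  ind <- pg$values[, pg$anchor_times >= w[1] & pg$anchor_times < w[1] + 10]
  par <- pg$values[, pg$anchor_times >= w[1] + 20 & pg$anchor_times < w[2]]
  mean_cor <- function(M) { cc <- stats::cor(M); mean(cc[upper.tri(cc)]) }
  expect_lt(mean_cor(par), mean_cor(ind))
  expect_gt(mean_cor(ind), 0.5)
})

test_that("noise-free Flat strips are identical without drift", {
  pulse_times <- seq(0, 4.9, by = 0.1)
  x <- synth_epoch_response(response_spec("Flat"), pulse_times, fs = 3000,
                            duration_s = 5.2, stim_s = 5, drift = FALSE)
  rec <- eeg_recording(x + 0, 3000)
  pg <- build_pulsogram(rec, pulse_times[2:49], y_window = c(-5, 60))
  expect_equal(max(apply(pg$values, 1, var)), 0)
})

test_that("stimulation-harmonic power dominates induction and collapses after the paroxysmal point", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 30, break_s = 30, pre_s = 5)
  out <- synth_optogenetic_recording(p, list(response_spec("SzKL", 8, 16, 40)),
                                     noise_spec(background_sd = 1e-3, seed = 2))
  hfrac <- function(from, to) {
    sp <- harmonic_decomposition(
      compute_spectrogram(crop_recording(out$recording, from, to), window_s = 1), 10)
    mean(sp$harmonic_power / sp$total_power)
  }
  expect_gt(hfrac(6, 13), 0.6)    # induction
  expect_lt(hfrac(22, 32), 0.5)   # paroxysmal
})

test_that("ground-truth phase markers are always ordered", {
  p <- stim_protocol(10, n_epochs = 6, train_s = 30, break_s = 90, pre_s = 15)
  set.seed(11)
  out <- synth_optogenetic_recording(p, batch_schedule(), noise_spec(seed = 11))
  for (m in out$markers) {
    present <- c(m$epoch_start, m$divergent, m$paroxysmal, m$seizure_end)
    present <- present[!is.na(present)]
    expect_true(all(diff(present) > 0))
  }
})

test_that("spontaneous recordings have the scheduled rate contrast and reproducible spikes", {
  out1 <- synth_spontaneous_recording(150, interictal_rate = 0.5,
                                      seizure_specs = list(c(100, 110, 130)),
                                      reverberant_rate = 5,
                                      noise = noise_spec(seed = 9))
  out2 <- synth_spontaneous_recording(150, interictal_rate = 0.5,
                                      seizure_specs = list(c(100, 110, 130)),
                                      reverberant_rate = 5,
                                      noise = noise_spec(seed = 9))
  expect_identical(out1$spike_times, out2$spike_times)
  expect_identical(out1$recording$samples, out2$recording$samples)
  # nominal ground-truth rate ratio is 10 by construction
  expect_equal(5 / 0.5, 10)
  gt_rev <- sum(out1$spike_times >= 100 & out1$spike_times < 110) / 10
  gt_ii <- sum(out1$spike_times >= 40 & out1$spike_times < 100) / 60
  expect_gt(gt_rev / gt_ii, 4)
  expect_error(synth_spontaneous_recording(100, interictal_rate = 0),
               "rates")
  expect_error(synth_spontaneous_recording(
    100, 0.5, list(c(10, 20, 40), c(30, 50, 60)), 5), "overlap")
})

test_that("the spike detector recovers injected spontaneous spikes", {
  out <- synth_spontaneous_recording(120, interictal_rate = 0.5,
                                     seizure_specs = list(),
                                     reverberant_rate = 5,
                                     noise = noise_spec(seed = 4))
  st <- detect_spikes(out$recording)
  hit <- vapply(out$spike_times, function(t)
    any(abs(st$spike_times - t) <= 0.005), logical(1))
  expect_gte(mean(hit), 0.9)
})
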