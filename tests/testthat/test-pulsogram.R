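test_that("pulsogram extraction is an exact re-slice of the raw samples", {
  fs <- 3000
  p <- stim_protocol(10, n_epochs = 1, train_s = 30, break_s = 2, pre_s = 1)
  set.seed(4)
  rec <- eeg_recording(rnorm(fs * 35), fs)
  pg <- build_pulsogram(rec, p)
  expect_equal(ncol(pg$values), 300L)
  expect_equal(nrow(pg$values), length(seq(round(-0.005 * fs), round(0.060 * fs))))
  for (k in c(1L, 57L, 300L)) {
    i0 <- round(pg$anchor_times[k] * fs) + 1L
    idx <- i0 + seq(round(-0.005 * fs), round(0.060 * fs))
    expect_identical(pg$values[, k], rec$samples[idx])
  }
})

test_that("a signal periodic at the pulse rate yields identical strips", {
  fs <- 3000
  p <- stim_protocol(10, n_epochs = 1, train_s = 10, break_s = 1, pre_s = 1)
  rec <- eeg_recording(sin(2 * pi * 10 * seq(0, 12, by = 1 / fs)), fs)
  pg <- build_pulsogram(rec, p)
  expect_equal(max(apply(pg$values, 1, var)), 0, tolerance = 1e-20)
})

test_that("extrapolated anchors continue at the pulse period past the train", {
  fs <- 3000
  p <- stim_protocol(10, n_epochs = 1, train_s = 10, break_s = 15, pre_s = 1)
  rec <- eeg_recording(rnorm(fs * 26), fs)
  pg0 <- build_pulsogram(rec, p)
  pg <- build_pulsogram(rec, p, extrapolate_s = 10)
  expect_equal(ncol(pg$values) - ncol(pg0$values), 100L)
  extra <- setdiff(pg$anchor_times, pg0$anchor_times)
  expect_equal(diff(extra), rep(0.1, 99), tolerance = 1e-9)
  expect_error(build_pulsogram(rec, numeric(0)), "empty anchor")
})

test_that("strips that exceed the recording are dropped with a message", {
  rec <- eeg_recording(rnorm(3000), 3000)
  expect_message(pg <- build_pulsogram(rec, c(0.5, 0.99)), "dropping 1")
  expect_equal(ncol(pg$values), 1L)
})

test_that("the spike detector keeps only the first peak of a multi-phasic discharge", {
  fs <- 3000
  set.seed(5)
  x <- rnorm(fs * 5)
  add_peak <- function(x, t, amp = 15) {
    idx <- round(t * fs) + seq_len(30)
    x[idx] <- x[idx] + amp * sin(pi * seq_len(30) / 30)
    x
  }
  x <- add_peak(x, 2.0)
  x <- add_peak(x, 2.015)    # 15 ms later: inside the refractory interval
  st <- detect_spikes(eeg_recording(x, fs))
  near <- st$spike_times[abs(st$spike_times - 2.0) < 0.05]
  expect_length(near, 1L)
  expect_lt(abs(near - 2.005), 0.01)   # the first peak is retained
})

test_that("plain Gaussian noise yields at most one spurious detection per minute", {
  set.seed(6)
  rec <- eeg_recording(rnorm(3000 * 60), 3000)
  st <- detect_spikes(rec)
  expect_lte(length(st$spike_times), 1L)
  expect_error(detect_spikes(eeg_recording(rep(0, 1000), 1000)), "zero")
})

test_that("injected spikes are recovered at the smoothed peak within one sample", {
  fs <- 3000
  set.seed(7)
  x <- rnorm(fs * 30)
  at <- seq(1, 29, length.out = 20)
  k <- sin(pi * seq_len(36) / 36)^2 * sin(2 * pi * seq_len(36) / 36)
  k <- 10 * k / max(k)
  for (t in at) {
    idx <- round(t * fs) + seq_along(k)
    x[idx] <- x[idx] + k
  }
  st <- detect_spikes(eeg_recording(x, fs))
  # brute-force oracle: smoothed argmax around each injection
  xs <- signal::sgolayfilt(x, p = 2, n = 31)
  for (t in at) {
    win <- round(t * fs) + seq_len(72)
    oracle_peak <- win[which.max(xs[win])]
    hit <- st$spike_times[abs(st$spike_times - (oracle_peak - 1) / fs) <= 1.5 / fs]
    expect_length(hit, 1L)
  }
})

test_that("spike detection equals the brute-force scan-and-filter oracle", {
  fs <- 2000
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(fs * 4)
    n_sp <- sample(0:6, 1)
    for (t in runif(n_sp, 0.2, 3.8)) {
      idx <- round(t * fs) + seq_len(24)
      x[idx] <- x[idx] + runif(1, 6, 14) * sin(pi * seq_len(24) / 24)
    }
    st <- detect_spikes(eeg_recording(x, fs))
    oracle <- spike_oracle(x, fs)
    expect_equal(round(st$spike_times * fs) + 1L, oracle)
  }
})

test_that("instantaneous power is flat for a sinusoid and scales as amplitude squared", {
  fs <- 3000
  t <- seq(0, 20, by = 1 / fs)
  x <- sin(2 * pi * 25 * t)
  anchors <- seq(1, 18, by = 0.25)
  rec1 <- eeg_recording(x, fs)
  pp1 <- power_pulsogram(rec1, anchors, reference_window = c(1, 5))
  # envelope power constant within 1%: all dB values near 0
  expect_lt(max(abs(pp1$values)), 10 * log10(1.01) * 3)
  # doubling the amplitude beyond the reference window adds 6.02 dB
  x2 <- x
  x2[t > 9.5] <- 2 * x2[t > 9.5]
  pp2 <- power_pulsogram(eeg_recording(x2, fs), anchors,
                         reference_window = c(1, 5))
  late <- pp2$anchor_times > 10 & pp2$anchor_times < 17
  expect_equal(mean(pp2$values[, late]), 10 * log10(4), tolerance = 0.05)
  expect_error(power_pulsogram(rec1, anchors, reference_window = c(19, 20)),
               "reference")
})

test_that("the reference region averages to the 0 dB level in linear power", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 10, break_s = 5, pre_s = 3)
  out <- synth_optogenetic_recording(p, list(response_spec("Flat")),
                                     noise_spec(seed = 10))
  pp <- power_pulsogram(out$recording, p, reference_window = c(3, 8))
  lin <- 10^(pp$values[, pp$reference_strips] / 10)
  expect_equal(mean(rowMeans(lin)), 1, tolerance = 1e-6)
})

test_that("kappa normalisation follows its closed forms", {
  fs <- 3000
  p <- stim_protocol(10, n_epochs = 1, train_s = 5, break_s = 1, pre_s = 1)
  n <- fs * 7
  # constant-power strips: all kappa equal sqrt(v0)
  rec <- eeg_recording(sin(2 * pi * 50 * seq(0, 7, by = 1 / fs))[1:n], fs)
  tm <- preprocess_trajectory(build_pulsogram(rec, p))
  expect_equal(tm$kappa, rep(sqrt(tm$mean_power), length(tm$kappa)),
               tolerance = 1e-6)
  expect_equal(tm$kappa, sqrt((tm$strip_power + tm$mean_power) / 2),
               tolerance = 1e-12)
  # one silent strip: kappa = sqrt(v0 / 2), no blow-up
  x <- sin(2 * pi * 50 * seq(0, 7, by = 1 / fs))[1:n]
  mask <- seq_len(n) > round(2.09 * fs) & seq_len(n) <= round(2.26 * fs)
  x[mask] <- 0
  tm2 <- preprocess_trajectory(build_pulsogram(eeg_recording(x, fs), p))
  silent <- which.min(tm2$strip_power)
  expect_lt(tm2$strip_power[silent] / tm2$mean_power, 0.05)
  expect_equal(tm2$kappa[silent],
               sqrt((tm2$strip_power[silent] + tm2$mean_power) / 2),
               tolerance = 1e-12)
})

test_that("normalisation attenuates spurious high-power strips boundedly", {
  # closed form: strip power after scaling is 2 v v0 / (v + v0)
  v0 <- 4
  v <- c(0.01, 1, 4, 100, 400) * v0
  scaled <- 2 * v * v0 / (v + v0)
  expect_true(all(diff(scaled) > 0))          # monotone in raw power
  expect_true(all(scaled < 2 * pmax(v, v0)))  # bounded attenuation
  expect_equal(scaled[4], 2 * v0 * (100 / 101), tolerance = 1e-12)
  # a strip 100x the mean keeps only ~2x the mean power after scaling
  expect_lt(scaled[4] / v0, 2)
})

test_that("delta power contrasts reverberant against induction per band", {
  p <- stim_protocol(10, n_epochs = 1, train_s = 30, break_s = 90, pre_s = 15)
  out <- synth_optogenetic_recording(p, list(response_spec("Evolving", 12)),
                                     noise_spec(seed = 101))
  g <- out$markers[[1]]
  pp <- power_pulsogram(out$recording, p, markers = g)
  d <- delta_power(pp, g, stim_end = p$epoch_windows[[1]][2])
  expect_gt(d$delta_late, 3)
  expect_lt(abs(d$delta_early), 1.5)
  # uniform offset: both bands shift equally (linearity)
  ppo <- pp
  shift <- pp$anchor_times >= g$divergent
  ppo$values[, shift] <- ppo$values[, shift] + 10 * log10(4)
  d2 <- delta_power(ppo, g, stim_end = p$epoch_windows[[1]][2])
  expect_equal(d2$delta_early - d$delta_early, 10 * log10(4), tolerance = 1e-9)
  expect_equal(d2$delta_late - d$delta_late, 10 * log10(4), tolerance = 1e-9)
  expect_error(delta_power(pp, phase_markers(15), 45), "divergent")
})
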