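# shared fixtures and independent oracles, all built in code

# minimal trajectory container for constructed toys
make_tm <- function(V, times = seq_len(ncol(V))) {
  structure(list(values = V, times = times), class = "trajectory_matrix")
}

# independent DTW oracle: plain recursive dynamic programme with
# memoisation, written without reference to the package implementation
dtw_oracle <- function(A, B) {
  n <- ncol(A); m <- ncol(B)
  D <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i, j] <- sqrt(sum((A[, i] - B[, j])^2))
  memo <- matrix(NA_real_, n, m)
  g <- function(i, j) {
    if (i == 1 && j == 1) return(D[1, 1])
    if (i < 1 || j < 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- min(if (i > 1 && j > 1) g(i - 1, j - 1) else Inf,
                if (i > 1) g(i - 1, j) else Inf,
                if (j > 1) g(i, j - 1) else Inf)
    memo[i, j] <<- best + D[i, j]
    memo[i, j]
  }
  g(n, m)
}

# independent RDP oracle: iterative stack-based simplification
rdp_oracle <- function(V, eps) {
  n <- ncol(V)
  keep <- c(1L, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j <= i + 1L) next
    a <- V[, i]; b <- V[, j]
    ab <- b - a
    L2 <- sum(ab^2)
    dmax <- -1; kmax <- NA_integer_
    for (k in (i + 1L):(j - 1L)) {
      p <- V[, k] - a
      dd <- if (L2 == 0) sqrt(sum(p^2)) else {
        tt <- sum(p * ab) / L2
        sqrt(sum((p - tt * ab)^2))
      }
      if (dd > dmax) { dmax <- dd; kmax <- k }
    }
    if (dmax > eps) {
      keep <- c(keep, kmax)
      stack <- c(stack, list(c(i, kmax)), list(c(kmax, j)))
    }
  }
  sort(unique(keep))
}

# independent spike-detection oracle: every local maximum of the smoothed
# trace, threshold filter, then left-to-right refractory filter
spike_oracle <- function(x, fs, k_mad = 6, refractory = 0.02, smooth = 0.01) {
  thr <- k_mad * median(abs(x))
  w <- round(smooth * fs); if (w %% 2 == 0) w <- w + 1
  xs <- signal::sgolayfilt(x, p = 2, n = w)
  n <- length(xs)
  pk <- which(c(FALSE, xs[2:(n - 1)] > xs[1:(n - 2)] &
                  xs[2:(n - 1)] >= xs[3:n], FALSE) & xs > thr)
  out <- integer(0)
  last <- -Inf
  for (p in pk) {
    if ((p - 1) / fs - last >= refractory) {
      out <- c(out, p)
      last <- (p - 1) / fs
    }
  }
  out
}

# the canonical multi-epoch batch schedule: one recording holds all five
# response types (epoch 1 must hold the first seizure)
batch_protocol <- function() stim_protocol(10, n_epochs = 6)

batch_schedule <- function(jitter = 0.5) {
  j <- function(x, a = jitter) x + runif(1, -a, a)
  list(response_spec("SzF", j(5), j(20), j(40), complexity_loops = 5),
       response_spec("Flat"),
       response_spec("Evolving", j(17)),
       response_spec("SzKS", j(14), j(26), j(34, 0.4)),
       response_spec("SzKL", j(7), j(18), j(45)),
       response_spec("Flat"))
}

# Trajectory metrics of the 50-recording synthetic batch, computed once and
# cached for the session (several acceptance properties share it).
batch_cache <- new.env(parent = emptyenv())

batch_metrics <- function(n_rec = 50) {
  key <- paste0("batch", n_rec)
  if (!is.null(batch_cache[[key]])) return(batch_cache[[key]])
  p <- batch_protocol()
  set.seed(20260922)
  out <- vector("list", n_rec)
  for (s in seq_len(n_rec)) {
    sim <- synth_optogenetic_recording(p, batch_schedule(),
                                       noise_spec(seed = 1000L + s))
    tm <- preprocess_trajectory(build_pulsogram(sim$recording, p))
    d_rec <- mean(sqrt(colSums(diff(t(tm$values))^2)))
    te <- lapply(seq_len(6), function(e)
      window_trajectory(tm, p$epoch_windows[[e]]))
    met <- sapply(seq_len(6), function(e) c(
      ang = angular_segmentation(te[[e]])$segment_count,
      rdp = rdp_segmentation(te[[e]], epsilon = 2 * d_rec)$segment_count,
      pc90 = pca_embed(te[[e]])$n_components_90))
    colnames(met) <- sim$labels
    dips <- vapply(list(c(2, 3), c(3, 4), c(4, 5)), function(pr) {
      dt <- dtw_compare(te[[pr[1]]], te[[pr[2]]])
      min(dt$coverage_ab[, "a_frac"] - dt$coverage_ab[, "b_frac"])
    }, numeric(1))
    ref <- vapply(2:6, function(e)
      dtw_compare(te[[1]], te[[e]])$distance, numeric(1))
    dist_kl <- vapply(c(4, 3, 2), function(e)
      dtw_compare(te[[5]], te[[e]])$distance, numeric(1)) / mean(ref)
    out[[s]] <- list(metrics = met, dips = dips, dist_kl = dist_kl,
                     schedule_markers = sim$markers, labels = sim$labels)
  }
  batch_cache[[key]] <- out
  out
}
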