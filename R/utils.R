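# shared numerical helpers

#' Analytic-signal envelope and instantaneous power
#'
#' Computes the amplitude envelope of a real signal as the modulus of its
#' analytic signal (Hilbert transform via FFT).  Instantaneous power is the
#' squared envelope; for a unit-amplitude sinusoid away from the edges the
#' instantaneous power is 1.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length as `x` (the envelope).
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# Savitzky-Golay smoothing with a window given in seconds.  Window is
# converted to an odd number of samples (>= order + 2, capped at series
# length).  sgolayfilt fits full least-squares polynomials at the edges, so
# no reflection padding leaks across strip boundaries.
sg_smooth <- function(x, width_s, rate, order = 2L) {
  n <- length(x)
  w <- round(width_s * rate)
  if (w %% 2L == 0L) w <- w + 1L
  w <- max(w, order + 2L + (order %% 2L))  # odd, > order
  if (w %% 2L == 0L) w <- w + 1L
  if (w >= n) {
    w <- if (n %% 2L == 0L) n - 1L else n
    if (w <= order) return(x)
  }
  signal::sgolayfilt(x, p = order, n = w)
}

# First index i such that `cond` holds at i and for at least `frac` of the
# window [i, i + k - 1]; NA_integer_ if never.  frac = 1 demands an
# unbroken run; the default tolerates isolated failing entries inside the
# sustain window.
first_sustained <- function(cond, k, frac = 0.9) {
  cond[is.na(cond)] <- FALSE
  n <- length(cond)
  if (k <= 1L) {
    i <- which(cond)
    return(if (length(i)) i[1L] else NA_integer_)
  }
  if (n < k) return(NA_integer_)
  need <- ceiling(frac * k)
  run <- cumsum(cond)
  counts <- run[k:n] - c(0, run[seq_len(n - k)])
  ok <- which(cond[seq_len(n - k + 1L)] & counts >= need)
  if (!length(ok)) return(NA_integer_)
  ok[1L]
}

# local minima of `x` below `max_value` with trough prominence >= `min_prom`.
# Prominence of a trough is computed on the negated series with the standard
# definition: height above the trough of the lowest saddle separating it from
# a deeper trough (or the series edge).
find_troughs <- function(x, max_value = Inf, min_prom = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  y <- -x
  # strict local maxima of y (plateau-aware: take first index of a plateau)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    higher_l <- which(y[seq_len(p - 1L)] > y[p])
    left <- if (length(higher_l)) min(y[max(higher_l):p]) else min(y[1:p])
    higher_r <- which(y[(p + 1L):n] > y[p]) + p
    right <- if (length(higher_r)) min(y[p:min(higher_r)]) else min(y[p:n])
    y[p] - max(left, right)
  }, numeric(1))
  keep <- x[cand] < max_value & prom >= min_prom
  cand[keep]
}

# centred moving average with partial windows at the edges (no NA)
runmean_partial <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
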