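# Trajectory analyses of preprocessed pulsograms: PCA embedding and latent
# dimensionality, DTW separation and nesting coverage, angular and RDP
# segmentation.  A trajectory is the strip sequence R[x] of a
# trajectory_matrix (columns = n-dimensional points).

traj_values <- function(x) {
  if (inherits(x, "trajectory_matrix")) x$values
  else if (is.matrix(x)) x
  else stop("expected a trajectory_matrix or a dims x points matrix",
            call. = FALSE)
}

traj_times <- function(x) {
  if (inherits(x, "trajectory_matrix")) x$times
  else seq_len(ncol(traj_values(x)))
}

#' PCA embedding of a response trajectory
#'
#' Principal component analysis over strips (strips are observations, pulse
#' times are variables).  Strips are mean-centred; no variance scaling is
#' applied since all strips share units after the kappa normalisation.
#' Latent dimensionality is summarised as the smallest number of components
#' whose cumulative explained variance reaches `var_target`.
#'
#' @param tm a [preprocess_trajectory()] result (or plain dims x strips
#'   matrix).  Use [window_trajectory()] first for per-epoch stimulation
#'   scope.
#' @param var_target cumulative explained-variance target (default 0.90).
#' @return object of class `pca_embedding`: `scores` (strips x components),
#'   `explained_variance_fraction` (non-increasing), `n_components_90`,
#'   `times`.
#' @export
pca_embed <- function(tm, var_target = 0.90) {
  V <- traj_values(tm)
  if (ncol(V) < 2L) stop("need at least 2 strips for PCA", call. = FALSE)
  pc <- prcomp(t(V), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  evf <- ev / sum(ev)
  structure(
    list(scores = pc$x, explained_variance_fraction = evf,
         n_components_90 = as.integer(which(cumsum(evf) >= var_target)[1]),
         rotation = pc$rotation, times = traj_times(tm),
         var_target = var_target),
    class = "pca_embedding")
}

#' @export
print.pca_embedding <- function(x, ...) {
  cat(sprintf("<pca_embedding> %d strips; PC1 %.1f%%, PC2 %.1f%%; %d PCs reach %.0f%%\n",
              nrow(x$scores), 100 * x$explained_variance_fraction[1],
              100 * (x$explained_variance_fraction[2] %||% 0),
              x$n_components_90, 100 * x$var_target))
  invisible(x)
}

#' @export
plot.pca_embedding <- function(x, main = "PCA trajectory", ...) {
  plot(x$scores[, 1], x$scores[, 2], type = "l",
       xlab = "PC1", ylab = "PC2", main = main, ...)
  invisible(x)
}

#' Dynamic time warping comparison of two trajectories
#'
#' Stretches and aligns two trajectories so that they are minimally
#' separated in Euclidean distance while maintaining the chronological order
#' of the points (classic symmetric steps, no windowing).  The separation
#' distance is the accumulated point-to-point Euclidean cost along the
#' optimal path.  Coverage curves express nesting: for each fraction of one
#' trajectory consumed by the warp, the fraction of the other consumed at
#' the same path position.  If trajectory `a` is a sub-segment of the
#' response contained in `b`, `a` is consumed faster and its coverage curve
#' lies on or above the diagonal.
#'
#' @param a,b trajectories (`trajectory_matrix` or dims x points matrices)
#'   with equal point dimensionality.
#' @return object of class `dtw_alignment`: `distance`, `path` (2-column
#'   index matrix), `coverage_ab` (fraction of `a` consumed vs fraction of
#'   `b`), `coverage_ba`, `coverage_at_80` (% of `a` consumed when `b` is
#'   80% consumed).
#' @export
dtw_compare <- function(a, b) {
  A <- traj_values(a); B <- traj_values(b)
  if (nrow(A) != nrow(B))
    stop("trajectories have different point dimensionality", call. = FALSE)
  aa <- colSums(A^2); bb <- colSums(B^2)
  D2 <- outer(aa, bb, `+`) - 2 * crossprod(A, B)
  D <- sqrt(pmax(D2, 0))
  res <- dtw_core(D)
  path <- cbind(res$index1, res$index2)
  n <- ncol(A); m <- ncol(B)
  # the coverage curve is single-valued: for each point of one trajectory,
  # the fraction of the other consumed once that point has been matched
  cov_curve <- function(x_idx, y_idx, nx, ny) {
    y_at <- vapply(seq_len(nx), function(j)
      max(y_idx[x_idx == j]), numeric(1))
    cbind(x = seq_len(nx) / nx, y = cummax(y_at) / ny)
  }
  cab <- cov_curve(path[, 2], path[, 1], m, n)
  cba <- cov_curve(path[, 1], path[, 2], n, m)
  colnames(cab) <- c("b_frac", "a_frac")
  colnames(cba) <- c("a_frac", "b_frac")
  i80 <- which(cab[, "b_frac"] >= 0.8)[1]
  structure(
    list(distance = res$distance, path = path,
         coverage_ab = cab, coverage_ba = cba,
         coverage_at_80 = 100 * cab[i80, "a_frac"],
         n_a = n, n_b = m),
    class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> %d vs %d points, distance %.4g, %.1f%% of A at 80%% of B\n",
              x$n_a, x$n_b, x$distance, x$coverage_at_80))
  invisible(x)
}

#' @export
plot.dtw_alignment <- function(x, main = "DTW coverage", ...) {
  plot(100 * x$coverage_ab[, 1], 100 * x$coverage_ab[, 2], type = "l",
       xlab = "% of trajectory B", ylab = "% of trajectory A",
       main = main, xlim = c(0, 100), ylim = c(0, 100), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Normalise DTW separation distances by the epoch-1 reference
#'
#' Variance between recording sessions is removed by dividing raw distances
#' by the average distance from the epoch-1 trajectory to all other epochs
#' of the same recording, so that average distance-to-epoch-1 is 1.0.
#'
#' @param distances numeric vector of raw separation distances (or a list of
#'   [dtw_compare()] results) to normalise.
#' @param reference_distances raw distances from the epoch-1 trajectory to
#'   every other epoch of the recording (at least 2).
#' @return numeric vector of normalised distances.
#' @export
normalize_distances <- function(distances, reference_distances) {
  if (is.list(distances))
    distances <- vapply(distances, function(d) d$distance, numeric(1))
  if (is.list(reference_distances))
    reference_distances <- vapply(reference_distances,
                                  function(d) d$distance, numeric(1))
  if (length(reference_distances) < 2L)
    stop("need the epoch-1 distances to at least 2 other epochs", call. = FALSE)
  distances / mean(reference_distances)
}

# Eq.-8 style mean step: average Euclidean distance between consecutive
# trajectory points
mean_step <- function(V) {
  if (ncol(V) < 2L) return(0)
  mean(sqrt(colSums((V[, -1L, drop = FALSE] - V[, -ncol(V), drop = FALSE])^2)))
}

#' Angular segmentation of a response trajectory
#'
#' Turning angles are computed at each point between the displacement from
#' the mean response over the preceding `window_s` and the displacement
#' towards the mean response over the following `window_s`; the reported
#' angle is 180 degrees minus the included angle, so a straight trajectory
#' scores 180 and a sharp direction reversal scores near 0.  Candidate
#' breakpoints are troughs of the angle series below `trough_max` with
#' prominence at least `prominence_min`.  A candidate is retained only if,
#' against the previously retained breakpoint: (i) it is separated by more
#' than `min_gap_s`; (ii) the adjacent segment means differ by more than
#' `d / sqrt(2)` in Euclidean norm, where `d` is the mean step between
#' consecutive points; and (iii) the adjacent segment means correlate below
#' 0.9 (i.e. the trough is not a short excursion within one overall trend).
#'
#' @param tm a `trajectory_matrix` (or dims x points matrix).
#' @param window_s averaging window for the turning angle, seconds.
#' @param trough_max angle ceiling for candidate troughs, degrees.
#' @param prominence_min minimum trough prominence, degrees.
#' @param min_gap_s minimum breakpoint separation, seconds.
#' @param max_corr segment-mean correlation ceiling.
#' @return object of class `segmentation`: `breakpoints` (seconds),
#'   `segment_count`, `turning_angles` (degrees, `NA` near the edges),
#'   `mean_step`, `method = "angular"`.
#' @export
angular_segmentation <- function(tm, window_s = 1, trough_max = 90,
                                 prominence_min = 30, min_gap_s = 0.67,
                                 max_corr = 0.9) {
  V <- traj_values(tm)
  tt <- traj_times(tm)
  nx <- ncol(V)
  if (nx < 3L || (tt[nx] - tt[1]) < 2 * window_s)
    stop("trajectory too short for angular segmentation", call. = FALSE)
  ang <- rep(NA_real_, nx)
  for (x in seq_len(nx)) {
    pre <- which(tt >= tt[x] - window_s & tt < tt[x])
    post <- which(tt > tt[x] & tt <= tt[x] + window_s)
    if (length(pre) < 2L || length(post) < 2L) next
    if (tt[x] - window_s < tt[1] || tt[x] + window_s > tt[nx]) next
    u <- V[, x] - rowMeans(V[, pre, drop = FALSE])
    v <- rowMeans(V[, post, drop = FALSE]) - V[, x]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) next
    cosang <- min(1, max(-1, sum(u * v) / (nu * nv)))
    ang[x] <- 180 - acos(cosang) * 180 / pi
  }
  finite <- which(!is.na(ang))
  cand <- integer(0)
  if (length(finite) >= 3L) {
    tr <- find_troughs(ang[finite], max_value = trough_max,
                       min_prom = prominence_min)
    cand <- finite[tr]
  }
  d <- mean_step(V)
  seg_mean <- function(i, j) rowMeans(V[, i:j, drop = FALSE])
  seg_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  kept <- integer(0)
  for (c in cand) {
    prev <- if (length(kept)) kept[length(kept)] else 1L
    prev0 <- if (length(kept) >= 2L) kept[length(kept) - 1L] else 1L
    if (tt[c] - tt[prev] <= min_gap_s && length(kept)) next
    m_new <- seg_mean(prev, c)
    m_old <- seg_mean(prev0, prev)
    if (length(kept)) {
      if (sqrt(sum((m_new - m_old)^2)) <= d / sqrt(2)) next
      if (seg_cor(m_new, m_old) >= max_corr) next
    } else {
      # first candidate: compare the segments it separates
      m_before <- seg_mean(1L, c)
      m_after <- seg_mean(c, nx)
      if (sqrt(sum((m_after - m_before)^2)) <= d / sqrt(2)) next
      if (seg_cor(m_after, m_before) >= max_corr) next
    }
    kept <- c(kept, c)
  }
  structure(
    list(breakpoints = tt[kept], breakpoint_index = kept,
         segment_count = length(kept) + 1L, turning_angles = ang,
         mean_step = d, n_points = nx, method = "angular"),
    class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation:%s> %d segment(s), breakpoints: %s\n",
              x$method, x$segment_count,
              if (length(x$breakpoints))
                paste(sprintf("%.2f", x$breakpoints), collapse = ", ")
              else "none"))
  invisible(x)
}

# perpendicular distance of column points P to the line through a and b
perp_dist <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  if (L2 == 0) return(sqrt(colSums((P - a)^2)))
  d <- P - a
  t <- as.numeric(crossprod(ab, d)) / L2
  proj <- outer(ab, t)
  sqrt(colSums((d - proj)^2))
}

rdp_keep <- function(V, i, j, eps) {
  if (j <= i + 1L) return(integer(0))
  mid <- (i + 1L):(j - 1L)
  dd <- perp_dist(V[, mid, drop = FALSE], V[, i], V[, j])
  k <- which.max(dd)
  if (dd[k] <= eps) return(integer(0))
  split <- mid[k]
  c(rdp_keep(V, i, split, eps), split, rdp_keep(V, split, j, eps))
}

#' Ramer-Douglas-Peucker segmentation of a trajectory
#'
#' Standard recursive farthest-point polyline simplification in the
#' n-dimensional strip space: vertices are retained until every discarded
#' point lies within `epsilon` perpendicular distance of the simplified
#' trajectory.  The segment count (retained vertices minus one) is an
#' alternative complexity measure cross-checking [angular_segmentation()].
#'
#' @param tm a `trajectory_matrix` (or dims x points matrix).
#' @param epsilon perpendicular-distance tolerance; defaults to twice the
#'   mean step between consecutive points, making the two segmenters
#'   comparable without hand tuning.
#' @return a `segmentation` object (`method = "rdp"`); `breakpoints` are the
#'   interior retained vertices.
#' @export
rdp_segmentation <- function(tm, epsilon = NULL) {
  V <- traj_values(tm)
  tt <- traj_times(tm)
  if (ncol(V) < 2L) stop("trajectory needs at least 2 points", call. = FALSE)
  if (is.null(epsilon)) epsilon <- 2 * mean_step(V)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  interior <- rdp_keep(V, 1L, ncol(V), epsilon)
  structure(
    list(breakpoints = tt[interior], breakpoint_index = interior,
         segment_count = length(interior) + 1L,
         turning_angles = NULL, mean_step = mean_step(V),
         epsilon = epsilon, n_points = ncol(V), method = "rdp"),
    class = "segmentation")
}
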