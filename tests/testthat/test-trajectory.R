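test_that("PCA embedding identifies rank and orders explained variance", {
  set.seed(1)
  pattern <- rnorm(12)
  V <- outer(pattern, runif(20, 0.5, 2))   # rank-1: scalar multiples
  pc <- pca_embed(make_tm(V))
  expect_equal(pc$n_components_90, 1L)
  expect_equal(pc$explained_variance_fraction[1], 1, tolerance = 1e-10)
  V2 <- matrix(rnorm(12 * 20), 12)
  evf <- pca_embed(make_tm(V2))$explained_variance_fraction
  expect_true(all(diff(evf) <= 1e-12))
  expect_lte(sum(evf), 1 + 1e-9)
  expect_error(pca_embed(make_tm(V2[, 1, drop = FALSE])), "2 strips")
})

test_that("PCA eigenvalues match a brute-force covariance eigendecomposition", {
  set.seed(2)
  for (i in 1:20) {
    V <- matrix(rnorm(8 * 20), 8)
    ev <- pca_embed(make_tm(V))$explained_variance_fraction
    lam <- eigen(cov(t(V)), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(ev, lam / sum(lam), tolerance = 1e-8)
  }
})

test_that("DTW satisfies identity, symmetry and matches the DP oracle", {
  set.seed(3)
  V <- matrix(rnorm(4 * 15), 4)
  self <- dtw_compare(V, V)
  expect_lt(self$distance, 1e-6)
  expect_equal(self$path[, 1], self$path[, 2])
  expect_equal(self$coverage_ab[, "a_frac"], self$coverage_ab[, "b_frac"])
  for (i in 1:25) {
    d <- sample(2:5, 1)
    A <- matrix(rnorm(d * sample(5:30, 1)), nrow = d)
    B <- matrix(rnorm(d * sample(5:30, 1)), nrow = d)
    d_ab <- dtw_compare(A, B)
    expect_equal(d_ab$distance, dtw_oracle(A, B), tolerance = 1e-10)
    expect_equal(d_ab$distance, dtw_compare(B, A)$distance, tolerance = 1e-10)
    # chronological order along the path
    expect_true(all(diff(d_ab$path[, 1]) >= 0))
    expect_true(all(diff(d_ab$path[, 2]) >= 0))
    expect_equal(d_ab$path[1, ], c(1, 1))
    expect_equal(d_ab$path[nrow(d_ab$path), ], c(ncol(A), ncol(B)))
  }
  expect_error(dtw_compare(matrix(0, 2, 4), matrix(0, 3, 4)), "dimensionality")
})

test_that("a nested trajectory is consumed faster than its extension", {
  # B = A followed by a distinct excursion
  set.seed(4)
  A <- rbind(seq(0, 1, length.out = 20), 0) + rnorm(40, sd = 0.002)
  excursion <- rbind(1 + seq(0.2, 3, length.out = 15),
                     seq(0.3, 4, length.out = 15))
  B <- cbind(A, excursion)
  dt <- dtw_compare(A, B)
  expect_true(all(dt$coverage_ab[, "a_frac"] >=
                    dt$coverage_ab[, "b_frac"] - 1e-12))
  # the fully nested prefix is exhausted by the time B is 80% consumed
  expect_equal(unname(dt$coverage_at_80), 100)
  # control: when A carries content B lacks, coverage at 80% stays partial
  A2 <- cbind(A, rbind(seq(1.2, 4, length.out = 25), -seq(1, 5, length.out = 25)))
  dt2 <- dtw_compare(A2, B)
  expect_lt(dt2$coverage_at_80, 100)
})

test_that("distance normalisation uses the epoch-1 average as the unit", {
  expect_equal(normalize_distances(6, c(2, 4)), 2)
  expect_equal(normalize_distances(0, c(2, 4)), 0)   # epoch 1 vs itself
  expect_equal(mean(normalize_distances(c(2, 4), c(2, 4))), 1)
  expect_error(normalize_distances(1, 2), "at least 2")
})

test_that("angular segmentation leaves a straight trajectory whole", {
  tt <- seq(0, 20, by = 0.1)
  V <- rbind(tt, 0.5 * tt, -tt)
  seg <- angular_segmentation(make_tm(V, tt))
  expect_equal(seg$segment_count, 1L)
  expect_length(seg$breakpoints, 0L)
  a <- seg$turning_angles
  expect_true(all(a[!is.na(a)] > 170))
  expect_error(angular_segmentation(make_tm(V[, 1:5], tt[1:5])), "short")
})

test_that("a single sharp corner yields one breakpoint near the corner", {
  tt <- seq(0, 20, by = 0.1)
  arm1 <- rbind(seq(0, 4, length.out = 100), 0)
  dir2 <- c(-1, 2) / sqrt(5)
  arm2 <- cbind(c(4, 0)) %*% rep(1, 101) +
    outer(dir2, seq(0, 10, length.out = 101))
  V <- cbind(arm1, arm2)
  seg <- angular_segmentation(make_tm(V, tt))
  expect_equal(seg$segment_count, 2L)
  expect_lt(abs(seg$breakpoints[1] - 10), 1)
})

test_that("corners closer than the minimum gap are not both retained", {
  tt <- seq(0, 20, by = 0.1)
  d1 <- c(1, 0); d2 <- c(-1.5, 1) / sqrt(3.25); d3 <- c(1, 1.2) / sqrt(2.44)
  p1 <- outer(d1, seq(0, 10, length.out = 100))
  c1 <- p1[, 100]
  p2 <- c1 + outer(d2, seq(0.1, 0.4, length.out = 4))
  c2 <- p2[, 4]
  p3 <- c2 + outer(d3, seq(0.1, 9.7, length.out = 97))
  V <- cbind(p1, p2, p3)
  seg <- angular_segmentation(make_tm(V, tt))
  expect_lte(length(seg$breakpoints), 1L)
})

test_that("RDP keeps a line minimal, everything at zero tolerance, and matches its oracle", {
  tt <- seq(0, 5, by = 0.25)
  line <- rbind(tt, 2 * tt)
  seg <- rdp_segmentation(make_tm(line, tt), epsilon = 0.1)
  expect_equal(seg$segment_count, 1L)
  set.seed(5)
  noisy <- line + rnorm(length(line), sd = 0.1)
  seg0 <- rdp_segmentation(make_tm(noisy, tt), epsilon = 0)
  expect_equal(seg0$segment_count, ncol(noisy) - 1L)   # all points retained
  expect_error(rdp_segmentation(make_tm(noisy, tt), epsilon = -1), "epsilon")
  for (i in 1:20) {
    P <- matrix(rnorm(2 * 30), 2)
    eps <- runif(1, 0.1, 2)
    mine <- rdp_segmentation(make_tm(P), epsilon = eps)
    oracle <- rdp_oracle(P, eps)
    expect_equal(sort(c(1L, mine$breakpoint_index, ncol(P))), oracle)
  }
})
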