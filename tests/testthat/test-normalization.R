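test_that("candidate_sequence matches hand arithmetic on small value lists", {
  # 5 values at 1 plus one at 100: mean 17.5, population var
  # (5*(1-17.5)^2 + (100-17.5)^2)/6 = 1361.25, so the first candidate
  # 17.5 + 4*sqrt(1361.25) = 165.08 already exceeds the maximum and the
  # guard stops the sequence at one record with no reduction.
  x <- c(1, 1, 1, 1, 1, 100)
  seq1 <- candidate_sequence(x)
  expect_equal(nrow(seq1), 1L)
  expect_equal(seq1$mean, 17.5)
  expect_equal(seq1$sd, sqrt(1361.25), tolerance = 1e-12)
  expect_equal(seq1$candidate_peak, 17.5 + 4 * sqrt(1361.25),
               tolerance = 1e-12)
  expect_true(is.na(seq1$z))

  # 99 values at 1 plus one at 50: first candidate 1.49 + 4*sqrt(23.7699)
  # = 20.99 < 99% of 50, so the outlier is excluded; the surviving set is
  # constant so the candidate collapses to 1 and converges there.
  y <- c(rep(1, 99), 50)
  m1 <- 1.49
  v1 <- (99 * (1 - m1)^2 + (50 - m1)^2) / 100
  seqy <- candidate_sequence(y)
  expect_equal(seqy$candidate_peak[1], m1 + 4 * sqrt(v1), tolerance = 1e-12)
  expect_gt(nrow(seqy), 1L)
  expect_equal(seqy$n_retained[2], 99L)
  expect_equal(seqy$candidate_peak[nrow(seqy)], 1)
  expect_gt(seqy$z[nrow(seqy)], 0.99)
})

test_that("degenerate inputs are handled: constants, short lists, non-finite", {
  s <- candidate_sequence(rep(3.2, 10))
  expect_equal(nrow(s), 1L)
  expect_equal(s$candidate_peak, 3.2)
  expect_error(candidate_sequence(5), "at least 2")
  expect_error(candidate_sequence(c(1, NA, 2)), "finite")
})

test_that("converge_peak applies the no-reduction guard on uniform lungs", {
  tp <- toy_pair(value = 5)
  res <- converge_peak(tp$volume, tp$mask)
  expect_false(res$reduction_applied)
  expect_equal(res$peak_intensity, 5)
  expect_equal(res$normalized_volume_fraction, 0)
  expect_equal(res$normalized_voxel_count, 0L)
  expect_identical(res$normalized$values, tp$volume$values)
})

test_that("zero-uptake voxels inside the mask enter the statistics", {
  vals <- array(0, c(4, 4, 4))
  vals[1:32] <- 2 # half the lung at 2, half at 0
  v <- uptake_volume(vals, c(4, 4, 4))
  m <- lung_mask(array(1, c(4, 4, 4)), template = v)
  res <- converge_peak(v, m)
  expect_equal(res$iterations$mean[1], 1) # (32*2 + 32*0)/64
  expect_equal(res$iterations$sd[1], 1)
})

test_that("hotspots are clipped to the converged peak and nothing else moves", {
  set.seed(101)
  n <- 1000
  bg <- rlnorm(n, 0, 0.3)
  hot_value <- 50 * mean(bg)
  vals <- array(c(bg[1:(n - 5)], rep(hot_value, 5)), c(10, 10, 10))
  v <- uptake_volume(vals, c(4, 4, 4))
  m <- lung_mask(array(1, c(10, 10, 10)), template = v)
  res <- converge_peak(v, m)

  expect_true(res$reduction_applied)
  expect_gte(nrow(res$iterations), 2L)
  expect_lt(res$peak_intensity, 2 * max(bg[1:(n - 5)]))
  # all five hotspot voxels clipped, to the peak exactly
  hot_idx <- which(vals == hot_value)
  expect_true(all(res$normalized$values[hot_idx] == res$peak_intensity))
  # clipping conservation: differences occur only above the peak
  diff_idx <- which(res$normalized$values != vals)
  expect_equal(length(diff_idx), res$normalized_voxel_count)
  expect_true(all(vals[diff_idx] > res$peak_intensity))
  expect_true(all(res$normalized$values[diff_idx] == res$peak_intensity))
  expect_gt(res$iterations$z[nrow(res$iterations)], 0.99)
})

test_that("converge_peak reuses the flat-list core verbatim", {
  set.seed(7)
  vals <- array(rlnorm(512, 0, 0.5), c(8, 8, 8))
  vals[1:6] <- 40
  v <- uptake_volume(vals, c(4, 4, 4))
  mask_arr <- array(rbinom(512, 1, 0.8), c(8, 8, 8))
  mask_arr[1:6] <- 1
  m <- lung_mask(mask_arr, template = v)
  res <- converge_peak(v, m)
  direct <- candidate_sequence(vals[mask_arr == 1])
  expect_equal(res$iterations, direct)
})

test_that("converge_peak is idempotent on its own output", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- array(rlnorm(1000, 0, 0.4), c(10, 10, 10))
    vals[1:3] <- 30 * mean(vals)
    v <- uptake_volume(vals, c(4, 4, 4))
    m <- lung_mask(array(1, c(10, 10, 10)), template = v)
    res <- converge_peak(v, m)
    res2 <- converge_peak(res$normalized, m)
    expect_false(res2$reduction_applied)
    expect_equal(res2$peak_intensity, res$peak_intensity)
    expect_equal(res2$normalized_voxel_count, 0L)
  }
})

test_that("peak convergence is scale equivariant", {
  set.seed(13)
  base <- rlnorm(2000, 0, 0.5)
  base[1:10] <- 25 * mean(base)
  for (c_mult in c(0.01, 3, 1e4)) {
    s1 <- candidate_sequence(base)
    s2 <- candidate_sequence(c_mult * base)
    expect_equal(nrow(s2), nrow(s1))
    expect_equal(s2$candidate_peak, c_mult * s1$candidate_peak,
                 tolerance = 1e-12)
    expect_equal(s2$z, s1$z, tolerance = 1e-12)
    expect_identical(s2$n_retained, s1$n_retained)
  }
})

test_that("candidate peaks decrease monotonically and converge quickly", {
  set.seed(29)
  for (rep in 1:20) {
    x <- random_uptake_sample(
      n = sample(100:5000, 1),
      outlier_fraction = runif(1, 0, 0.05),
      outlier_multiple = runif(1, 5, 100))
    s <- candidate_sequence(x)
    expect_lte(nrow(s), 10L)
    expect_true(all(diff(s$candidate_peak) <= 1e-12))
    expect_true(all(s$z[-1] <= 1 + 1e-12))
    expect_true(nrow(s) == 1L || s$z[nrow(s)] > 0.99)
  }
})

test_that("a large Gaussian sample yields a strictly decreasing sequence", {
  set.seed(4242)
  x <- rnorm(1e5)
  s <- candidate_sequence(x)
  expect_gt(nrow(s), 1L)
  expect_lte(nrow(s), 10L)
  expect_true(all(diff(s$candidate_peak) < 0))
  ref <- reference_candidate_sequence(x)
  expect_equal(nrow(s), nrow(ref))
  expect_equal(s$candidate_peak, ref$candidate_peak, tolerance = 1e-12)
})

test_that("geometry and mask preconditions are enforced", {
  tp <- toy_pair()
  wrong <- lung_mask(array(1, c(6, 6, 7)), spacing = c(4, 4, 4))
  expect_error(converge_peak(tp$volume, wrong), "geometry")
  single <- lung_mask(array(c(1, rep(0, 215)), c(6, 6, 6)),
                      spacing = c(4, 4, 4))
  expect_error(converge_peak(tp$volume, single), "at least 2")
})

test_that("sigma multiplier and convergence cutoff overrides propagate", {
  set.seed(55)
  vals <- array(rlnorm(1000, 0, 0.5), c(10, 10, 10))
  vals[1] <- 50 * mean(vals)
  v <- uptake_volume(vals, c(4, 4, 4))
  m <- lung_mask(array(1, c(10, 10, 10)), template = v)
  # a large enough multiplier places the first candidate above any value,
  # so no reduction can ever occur
  res <- converge_peak(v, m, sigma_multiplier = 1000)
  expect_false(res$reduction_applied)
  res2 <- converge_peak(v, m, sigma_multiplier = 4)
  expect_true(res2$reduction_applied)
})
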