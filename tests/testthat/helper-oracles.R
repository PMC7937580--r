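# Independent from-scratch reference for the iterative peak convergence.
# Tracks explicit voxel indices and recomputes all statistics from the raw
# retained subset at every pass; shares no code with candidate_sequence().
reference_candidate_sequence <- function(values, k = 4, cutoff = 0.99,
                                         max_iter = 100) {
  keep <- seq_along(values)
  orig_max <- max(values)
  rows <- list()
  prev <- NA_real_
  for (i in seq_len(max_iter)) {
    x <- values[keep]
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / n)
    cand <- m + k * s
    z <- if (i == 1) NA_real_ else cand / prev
    rows[[i]] <- data.frame(iteration = i, n_retained = n, mean = m, sd = s,
                            candidate_peak = cand, z = z)
    if (i == 1) {
      if (cand >= orig_max || (orig_max - cand) / orig_max < (1 - cutoff)) break
    } else if (z > cutoff) {
      break
    }
    keep <- keep[values[keep] <= cand]
    prev <- cand
  }
  do.call(rbind, rows)
}

# random flat uptake sample: lognormal background with a controllable
# fraction of injected outliers at a stated multiple of the background mean
random_uptake_sample <- function(n, outlier_fraction, outlier_multiple,
                                 meanlog = 0, sdlog = 0.4) {
  x <- rlnorm(n, meanlog, sdlog)
  n_out <- round(outlier_fraction * n)
  if (n_out > 0) {
    x[seq_len(n_out)] <- outlier_multiple * mean(x)
  }
  x
}

# small uniform-cube volume + full mask pair for quick geometry-level tests
toy_pair <- function(value = 5, shape = c(6, 6, 6), spacing = c(4, 4, 4)) {
  v <- uptake_volume(array(value, shape), spacing = spacing)
  m <- lung_mask(array(1, shape), template = v)
  list(volume = v, mask = m)
}

# tiny fast phantom spec for tests that only need structure, not realism
tiny_spec <- function(seed, ...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), spacing = c(8, 8, 8),
               seed = seed, ...)
}
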