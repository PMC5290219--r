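# Shared fixtures and independent oracles for the test suite.

# Noise-free generator configuration: pure task response, no drift,
# oscillations or measurement noise.
quiet_config <- function(noise_sd = 0, physio_amplitudes = c(0, 0, 0),
                         drift_coeffs = c(0, 0), ...) {
  simulation_config(noise_sd = noise_sd, physio_amplitudes = physio_amplitudes,
                    drift_coeffs = drift_coeffs, ...)
}

# Sum-of-distances objective of the geometric-median problem.
sum_dist <- function(y, pts) sum(sqrt(colSums((t(pts) - y)^2)))

# Independent brute-force minimizer of the geometric-median objective:
# coarse-to-fine grid search, zooming three times. Exponential in the
# dimension, so only for <= 3-D instances.
gm_grid_oracle <- function(X, levels = 6L, pts = 21L) {
  d <- ncol(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- pmax(hi - lo, 1e-9)
  lo <- lo - 0.05 * span; hi <- hi + 0.05 * span
  best <- (lo + hi) / 2
  for (lev in seq_len(levels)) {
    grids <- lapply(seq_len(d), function(j) seq(lo[j], hi[j], length.out = pts))
    cand <- as.matrix(expand.grid(grids))
    objs <- apply(cand, 1, sum_dist, pts = X)
    best <- cand[which.min(objs), ]
    step <- (hi - lo) / (pts - 1)
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  list(point = as.numeric(best), objective = sum_dist(as.numeric(best), X))
}

# Two well-separated Gaussian feature clusters (gap >= 5 noise SD).
separated_clusters <- function(n_per = 15L, dim = 3L, gap = 6, sd = 1,
                               seed = 1L) {
  set.seed(seed)
  X0 <- matrix(stats::rnorm(n_per * dim, mean = 1, sd = sd), ncol = dim)
  X1 <- matrix(stats::rnorm(n_per * dim, mean = 1 + gap * sd, sd = sd), ncol = dim)
  list(X = rbind(X0, X1), y = rep(c(0L, 1L), each = n_per))
}

# Small preprocessed cohort cached per test run.
small_preprocessed_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 10L, seed = 42L) {
    key <- paste(n, seed)
    if (is.null(cache[[key]])) {
      cohort <- generate_cohort(simulation_config(n_participants = n, seed = seed))
      cache[[key]] <- preprocess_cohort(cohort)
    }
    cache[[key]]
  }
})
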