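# Small fixtures shared across test files. Everything is generated in
# code under fixed seeds; nothing is stored on disk.

# depth model with a flat GC adjustment (single bin), for unit tests
flat_depth_model <- function(lam) {
  structure(list(lam = lam, gc_window = 100L, n_bins = 1L, G = 1,
                 bin_counts = 0L),
            class = "depth_model")
}

# compact HMM over a narrow insert model, cheap enough for per-position
# R-level emission checks
tiny_hmm <- function(D = 50, sigma = 5, cutoff = 200, lam = 0.2,
                     grid_sizes = c(10, 20), het_mix_weight = 0.5,
                     genome_len = 1000) {
  im <- insert_model_gaussian(D, sigma, dist_cutoff = cutoff)
  build_hmm(im, flat_depth_model(lam), genome_len = genome_len,
            grid_sizes = grid_sizes, het_mix_weight = het_mix_weight)
}

# exhaustive-enumeration decoder: the independent oracle for Viterbi.
# Accumulates log-probabilities along each path left to right (the same
# association order as the DP recursion).
enumerate_best_path <- function(logE, logT, logInit) {
  S <- nrow(logE)
  T_ <- ncol(logE)
  best <- -Inf
  grid <- do.call(expand.grid, rep(list(seq_len(S)), T_))
  for (r in seq_len(nrow(grid))) {
    p <- as.integer(grid[r, ])
    ll <- logInit[p[1]] + logE[p[1], 1]
    if (T_ > 1) {
      for (t in 2:T_) ll <- (ll + logT[p[t - 1], p[t]]) + logE[p[t], t]
    }
    if (ll > best) best <- ll
  }
  best
}

# one standard small simulation reused by several tests
std_sim <- function(ref_len = 5e5, n_del = 20, coverage = 3, seed = 42,
                    libraries = list(c(1500, 200)), ...) {
  cfg <- sim_config(ref_len = ref_len, n_del = n_del,
                    del_sizes = c(400, 800), coverage = coverage,
                    libraries = libraries, seed = seed, ...)
  simulate_dataset(cfg)
}

# Monte-Carlo oracle for the depth-only calculator: the discrete
# critical value is re-derived from direct Poisson pmf summation
# (independent of the implementation's quantile search) and the power
# is estimated from alternative-hypothesis draws.
mc_depth_power <- function(delta, lam, S = 35, alpha = 1e-5,
                           n_draws = 1e5) {
  mu0 <- delta * lam / S
  pm <- exp(-mu0)
  cum <- pm
  k <- 0
  while (cum <= alpha && k < 10 * mu0 + 100) {
    k <- k + 1
    pm <- pm * mu0 / k
    cum <- cum + pm
  }
  k <- k - 1  # largest k with lower-tail mass <= alpha (-1 if none)
  if (k < 0) return(list(power = 0, se = 0))
  draws <- rpois(n_draws, 0.5 * mu0)
  list(power = mean(draws <= k), se = sqrt(alpha / n_draws + 1e-12))
}

# Monte-Carlo oracle for the multi-pair calculator: m spanning inserts
# of the carrier haplotype, each shifted by the deletion size, tested
# with the one-sided Z statistic against the known null.
mc_multi_pair_power <- function(delta, m, D, sigma, alpha = 1e-5,
                                n_rep = 1e5) {
  z_crit <- qnorm(1 - alpha)
  draws <- matrix(rnorm(n_rep * m, D + delta, sigma), nrow = m)
  z <- (colMeans(draws) - D) / (sigma / sqrt(m))
  mean(z > z_crit)
}

empty_reads_fixture <- function() parse_mapview(character(0))
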