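# Shared builders for test fixtures. Pixel scale 0.13 mm/px makes the
# default 10 px^2/Hz detection threshold ~0.169 mm^2/Hz.
PX <- 0.13

# A trajectory whose x and y series are the same k sinusoids (amplitudes in
# mm, frequencies in Hz), i.e. a spirograph-like motif with k resolvable
# harmonics per axis.
harmonic_traj <- function(freqs, amps = rep(0.5, length(freqs)),
                          noise_sd = 0.005, seed = 1, duration = 1800, fs = 1) {
  comp <- data.frame(amplitude = amps, frequency = freqs,
                     phase = rep(0, length(freqs)))
  compy <- transform(comp, phase = -pi / 2)
  simulate_trajectory(trajectory_sim_spec(
    "multi_harmonic", components = list(x = comp, y = compy),
    duration = duration, sampling_rate = fs, noise_sd = noise_sd, seed = seed))
}

# Brute-force one-sided periodogram (independent DFT oracle; no fft()).
periodogram_oracle <- function(z, fs) {
  n <- length(z)
  z <- z - mean(z)
  nf <- floor(n / 2) + 1L
  t <- 0:(n - 1)
  power <- vapply(seq_len(nf), function(k) {
    w <- 2 * pi * (k - 1) / n
    re <- sum(z * cos(w * t)); im <- sum(z * sin(w * t))
    p <- (re^2 + im^2) / (fs * n)
    dbl <- if (k == 1L || (n %% 2L == 0L && k == nf)) 1 else 2
    p * dbl
  }, numeric(1))
  list(frequencies = (seq_len(nf) - 1) * fs / n, power = power)
}

# Identical-law two-group pooled-expression null simulation.
null_pooled_sim <- function(n_genes, seed, individual_cv = 0.4,
                            n_pools = 3, pool_size = 10) {
  simulate_pooled_expression(pooled_sim_spec(
    n_genes,
    groups = list(
      g1 = list(n_pools = n_pools, pool_size = pool_size, individual_cv = individual_cv),
      g2 = list(n_pools = n_pools, pool_size = pool_size, individual_cv = individual_cv)),
    seed = seed))
}

bin_fraction_run <- function(sim, cfg) {
  f <- filter_genes(sim)
  g <- unique(f$group)
  bin_fractions(pooled_cv(f, g[1]), pooled_cv(f, g[2]), cfg)
}
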