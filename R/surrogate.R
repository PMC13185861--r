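#' Surrogate validation configuration
#'
#' @param n_surrogates Number of phase-randomized surrogate series (>= 20).
#' @param percentile Significance percentile of the surrogate wavelet-power
#'   distribution, in (50, 100). Default 95.
#' @param wavelet Mother wavelet; currently the analytic Morlet
#'   (`omega0 = 6`).
#' @param seed Integer RNG seed for the surrogate phases.
#' @param dj Scale resolution in octaves (smaller = finer scale grid).
#' @return A `surrogate_config` object.
#' @export
surrogate_config <- function(n_surrogates = 200, percentile = 95,
                             wavelet = "morlet", seed = 1L, dj = 0.125) {
  if (n_surrogates < 20) stop("n_surrogates must be >= 20")
  if (percentile <= 50 || percentile >= 100) stop("percentile must be in (50, 100)")
  wavelet <- match.arg(wavelet)
  structure(list(n_surrogates = as.integer(n_surrogates),
                 percentile = percentile, wavelet = wavelet,
                 seed = as.integer(seed), dj = dj),
            class = "surrogate_config")
}

# Analytic Morlet (omega0 = 6) continuous wavelet transform, computed in the
# Fourier domain with zero padding to the next power of two to limit
# wrap-around. Returns the time-averaged wavelet power per scale (averaged
# over the original, unpadded samples) and the scale centre frequencies.
morlet_avg_power <- function(z, fs, dj = 0.125) {
  n <- length(z)
  dt <- 1 / fs
  omega0 <- 6
  npad <- 2^ceiling(log2(n))
  zp <- c(z - mean(z), rep(0, npad - n))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  Z <- stats::fft(zp)
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  s0 <- 2 * dt
  J <- floor(log2(n * dt / s0) / dj)
  scales <- s0 * 2^(dj * (0:J))
  avg <- vapply(scales, function(s) {
    psihat <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * omega - omega0)^2) / 2) * (omega > 0)
    W <- stats::fft(Z * psihat, inverse = TRUE)[seq_len(n)] / npad
    mean(Mod(W)^2)
  }, numeric(1))
  list(scales = scales, frequencies = 1 / (fourier_factor * scales), avg_power = avg)
}

#' Phase-randomized surrogate of a time series
#'
#' Fourier-transforms the series, replaces the phases of all non-DC (and
#' non-Nyquist) bins with i.i.d. uniform phases under Hermitian symmetry,
#' and inverts. The surrogate preserves the amplitude spectrum (hence the
#' mean and variance) of the original exactly while destroying its phase
#' structure.
#'
#' @param z Numeric series.
#' @return A real series of the same length.
#' @export
phase_randomize <- function(z) {
  n <- length(z)
  X <- stats::fft(z)
  half <- floor((n - 1) / 2)
  if (half >= 1) {
    idx <- 2:(half + 1)
    phi <- stats::runif(half, 0, 2 * pi)
    X[idx] <- Mod(X[idx]) * exp(1i * phi)
    X[n + 2 - idx] <- Conj(X[idx])
  }
  if (n %% 2 == 0) {
    # Nyquist bin must stay real; a random sign keeps |X| and realness
    X[n / 2 + 1] <- Mod(X[n / 2 + 1]) * sample(c(-1, 1), 1)
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Validate spectral peaks against phase-randomized surrogates
#'
#' For each axis the detrended coordinate series is wavelet-transformed
#' (analytic Morlet) and its time-averaged wavelet power per scale is
#' compared against the same statistic computed on `n_surrogates`
#' phase-randomized surrogates, which preserve the amplitude spectrum but
#' randomize phase. Per scale, the significance threshold is the configured
#' percentile of the surrogate distribution; a Welch peak passes when the
#' observed power at the scale whose centre frequency is nearest the peak
#' frequency exceeds that threshold. Peaks outside the wavelet scale range
#' are flagged `"untestable"` rather than failed.
#'
#' @param traj The [trajectory()] the peaks came from.
#' @param peaks A `complexity_result` (from [complexity_index()] or
#'   [trajectory_complexity()]) or a `spectral_peaks` data.frame.
#' @param cfg A [surrogate_config()].
#' @return A `data.frame` of class `surrogate_validation` with columns
#'   `axis`, `peak_frequency`, `scale_frequency`, `observed_power`,
#'   `threshold`, `pass`, `status`.
#' @export
surrogate_validate <- function(traj, peaks, cfg = surrogate_config()) {
  stopifnot(inherits(traj, "bot_trajectory"), inherits(cfg, "surrogate_config"))
  tab <- if (inherits(peaks, "complexity_result")) peaks$peaks else as.data.frame(peaks)
  out <- tab[0, c("axis", "frequency"), drop = FALSE]
  res <- list()
  local_seed(cfg$seed, {
    for (ax in unique(tab$axis)) {
      z <- traj[[ax]]
      z <- z - mean(z)
      obs <- morlet_avg_power(z, traj$sampling_rate, cfg$dj)
      surr <- matrix(NA_real_, nrow = length(obs$scales), ncol = cfg$n_surrogates)
      for (b in seq_len(cfg$n_surrogates))
        surr[, b] <- morlet_avg_power(phase_randomize(z), traj$sampling_rate,
                                      cfg$dj)$avg_power
      thr <- apply(surr, 1L, stats::quantile, probs = cfg$percentile / 100,
                   names = FALSE)
      fpk <- tab$frequency[tab$axis == ax]
      frange <- range(obs$frequencies)
      for (f in fpk) {
        if (f < frange[1L] || f > frange[2L]) {
          res[[length(res) + 1L]] <- data.frame(
            axis = ax, peak_frequency = f, scale_frequency = NA_real_,
            observed_power = NA_real_, threshold = NA_real_,
            pass = NA, status = "untestable", stringsAsFactors = FALSE)
        } else {
          i <- which.min(abs(log(obs$frequencies) - log(f)))
          res[[length(res) + 1L]] <- data.frame(
            axis = ax, peak_frequency = f,
            scale_frequency = obs$frequencies[i],
            observed_power = obs$avg_power[i], threshold = thr[i],
            pass = obs$avg_power[i] > thr[i], status = "tested",
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(axis = character(), peak_frequency = numeric(),
               scale_frequency = numeric(), observed_power = numeric(),
               threshold = numeric(), pass = logical(), status = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("surrogate_validation", "data.frame")
  out
}
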