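test_that("pure-tone PSD integrates to A^2/2 (Parseval, boxcar single window)", {
  tr <- harmonic_traj(freqs = 0.01, amps = 1, noise_sd = 0, duration = 1800)
  ps <- welch_psd(tr, welch_config(window_s = 1800, overlap_s = 0, taper = "boxcar"))
  expect_equal(sum(ps$x$power) * ps$x$df, 0.5, tolerance = 0.01)
  expect_equal(sum(ps$y$power) * ps$y$df, 0.5, tolerance = 0.01)
})

test_that("a constant signal has essentially no power after mean detrend", {
  tr <- trajectory(rep(2, 900), rep(-1, 900), sampling_rate = 1)
  ps <- welch_psd(tr, welch_config())
  expect_lt(max(ps$x$power), 1e-20)
  expect_lt(max(ps$y$power), 1e-20)
})

test_that("single-window boxcar Welch equals the brute-force periodogram oracle", {
  tr <- harmonic_traj(freqs = c(0.013, 0.041), amps = c(0.5, 0.2),
                      noise_sd = 0.05, seed = 6, duration = 256)
  ps <- welch_psd(tr, welch_config(window_s = 256, overlap_s = 0, taper = "boxcar"))
  oracle <- periodogram_oracle(tr$x, 1)
  expect_equal(ps$x$frequencies, oracle$frequencies)
  expect_equal(ps$x$power, oracle$power, tolerance = 1e-8)
})

test_that("peak location is taper-invariant for a resolvable tone", {
  tr <- harmonic_traj(freqs = 0.02, amps = 1, noise_sd = 0.01, seed = 2)
  for (tp in c("hann", "boxcar")) {
    ps <- welch_psd(tr, welch_config(taper = tp))
    pk <- detect_peaks(ps$x, 10, PX)
    expect_equal(nrow(pk), 1L)
    expect_equal(pk$frequency, ps$x$frequencies[which.min(abs(ps$x$frequencies - 0.02))])
  }
})

test_that("a flat spectrum below threshold yields no peaks", {
  tr <- simulate_trajectory(trajectory_sim_spec("stationary", noise_sd = 0.01,
                                                seed = 1))
  ps <- welch_psd(tr)
  expect_equal(nrow(detect_peaks(ps$x, 10, PX)), 0L)
})

test_that("two tones separated by >= 3 bins give exactly two peaks", {
  tr <- harmonic_traj(freqs = c(0.01, 0.03), noise_sd = 0.005, seed = 4)
  ps <- welch_psd(tr)
  pk <- detect_peaks(ps$x, 10, PX)
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$frequency), c(0.01, 0.03), tolerance = ps$x$df)
})

test_that("recordings shorter than the window fall back to one flagged segment", {
  tr <- harmonic_traj(freqs = 0.05, noise_sd = 0, duration = 200)
  ps <- welch_psd(tr, welch_config(window_s = 400))
  expect_true(ps$x$full_length_fallback)
  expect_equal(ps$x$n_segments, 1L)
})

test_that("CI definitional anchors: circle = 1, stationary = 0, split peaks add", {
  circ <- simulate_trajectory(trajectory_sim_spec("circle", noise_sd = 0.01, seed = 5))
  expect_equal(trajectory_complexity(circ, pixel_scale = PX)$ci, 1L)
  still <- simulate_trajectory(trajectory_sim_spec("stationary", noise_sd = 0.01, seed = 5))
  expect_equal(trajectory_complexity(still, pixel_scale = PX)$ci, 0L)
  # x has one peak, y shares it and adds a second far one -> CI = 2
  spec <- trajectory_sim_spec("multi_harmonic", components = list(
    x = data.frame(amplitude = 0.5, frequency = 0.01, phase = 0),
    y = data.frame(amplitude = c(0.5, 0.4), frequency = c(0.01, 0.04),
                   phase = c(-pi / 2, 0))), noise_sd = 0.005, seed = 5)
  expect_equal(trajectory_complexity(simulate_trajectory(spec), pixel_scale = PX)$ci, 2L)
})

test_that("unique-peak union merges frequencies within the matching tolerance", {
  mk <- function(axis, f, p) {
    structure(data.frame(axis = rep(axis, length(f)), frequency = f, power = p),
              class = c("spectral_peaks", "data.frame"),
              df = 0.0025, threshold_px2 = 10, threshold_mm2 = 0.169)
  }
  # same frequency on both axes -> one unique peak
  expect_equal(complexity_index(mk("x", 0.01, 1), mk("y", 0.01, 1))$ci, 1L)
  # empty
  expect_equal(complexity_index(mk("x", numeric(), numeric()),
                                mk("y", numeric(), numeric()))$ci, 0L)
  # off by one bin -> merged; far apart -> counted separately
  expect_equal(complexity_index(mk("x", 0.01, 1), mk("y", 0.0125, 1))$ci, 1L)
  expect_equal(complexity_index(mk("x", 0.01, 1), mk("y", c(0.01, 0.04), c(1, 1)))$ci, 2L)
})

test_that("raising the detection threshold never increases CI", {
  tr <- harmonic_traj(freqs = c(0.01, 0.025, 0.04), amps = c(0.6, 0.3, 0.15),
                      noise_sd = 0.02, seed = 11)
  ci <- vapply(c(1, 10, 100, 1000, 1e5), function(thr)
    trajectory_complexity(tr, threshold_px2_per_hz = thr, pixel_scale = PX)$ci,
    integer(1))
  expect_true(all(diff(ci) <= 0))
  expect_equal(ci[length(ci)], 0L)
})

test_that("CI is invariant to translation, axis swap and circular time shift", {
  tr <- harmonic_traj(freqs = c(0.01, 0.03), noise_sd = 0, seed = 1)
  ci0 <- trajectory_complexity(tr, pixel_scale = PX)$ci
  shift <- trajectory(tr$x + 10, tr$y - 4, 1)
  expect_equal(trajectory_complexity(shift, pixel_scale = PX)$ci, ci0)
  swap <- trajectory(tr$y, tr$x, 1)
  expect_equal(trajectory_complexity(swap, pixel_scale = PX)$ci, ci0)
  k <- 200
  rot <- trajectory(c(tr$x[-(1:k)], tr$x[1:k]), c(tr$y[-(1:k)], tr$y[1:k]), 1)
  expect_equal(trajectory_complexity(rot, pixel_scale = PX)$ci, ci0)
})

test_that("relative complexity is the difference from the control mean", {
  expect_equal(relative_complexity(2, c(2, 2, 2)), 0)
  expect_equal(relative_complexity(3, c(1, 1, 1)), 2)
  expect_equal(relative_complexity(0, c(2, 1, 3)), -2)
  expect_error(relative_complexity(1, numeric()), "control")
})
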