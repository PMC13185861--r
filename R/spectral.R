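#' Welch estimator configuration
#'
#' Defaults follow the movement analysis this package implements: 400-s
#' windows with 1 s of overlap, a Hann taper and per-segment mean removal.
#' The frequency resolution of the resulting spectrum is `1/window_s`.
#'
#' @param window_s Segment length in s.
#' @param overlap_s Overlap between consecutive segments in s
#'   (`0 <= overlap_s < window_s`).
#' @param taper `"hann"` or `"boxcar"`.
#' @param detrend Per-segment detrending: `"mean"` or `"linear"`.
#' @return A `welch_config` object.
#' @export
welch_config <- function(window_s = 400, overlap_s = 1,
                         taper = c("hann", "boxcar"),
                         detrend = c("mean", "linear")) {
  taper <- match.arg(taper); detrend <- match.arg(detrend)
  stop_if_not_scalar_number(window_s, "window_s", positive = TRUE)
  stop_if_not_scalar_number(overlap_s, "overlap_s")
  if (overlap_s < 0 || overlap_s >= window_s)
    stop("need 0 <= overlap_s < window_s")
  structure(list(window_s = window_s, overlap_s = overlap_s,
                 taper = taper, detrend = detrend),
            class = "welch_config")
}

welch_one <- function(z, fs, cfg) {
  n <- length(z)
  if (n < 8L) stop("fewer than 8 samples")
  L <- round(cfg$window_s * fs)
  if (L < 8L) stop("window_s x sampling_rate must be at least 8 samples")
  fallback <- FALSE
  if (L > n) {            # short recording: one full-length segment, flagged
    L <- n
    fallback <- TRUE
  }
  hop <- max(1L, round((cfg$window_s - cfg$overlap_s) * fs))
  starts <- seq(1L, n - L + 1L, by = if (fallback) L else hop)
  w <- if (cfg$taper == "hann") {
    0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))  # periodic Hann
  } else rep(1, L)
  scale <- fs * sum(w^2)
  nf <- floor(L / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- z[s:(s + L - 1L)]
    seg <- if (cfg$detrend == "mean") seg - mean(seg) else detrend_linear(seg)
    X <- stats::fft(w * seg)[seq_len(nf)]
    P <- (Mod(X)^2) / scale
    # one-sided density: double everything except DC (and Nyquist when L even)
    dbl <- rep(2, nf); dbl[1L] <- 1
    if (L %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + P * dbl
  }
  list(frequencies = (seq_len(nf) - 1) * fs / L,
       power = acc / length(starts),
       df = fs / L, n_segments = length(starts), full_length_fallback = fallback)
}

detrend_linear <- function(z) {
  t <- seq_along(z)
  stats::lm.fit(cbind(1, t), z)$residuals
}

#' Welch power spectral density of the x and y coordinate series
#'
#' Estimates one-sided power spectral densities (mm^2/Hz) per axis; the
#' integral of each spectrum over frequency approximates the variance of the
#' corresponding coordinate series. Recordings shorter than `window_s` are
#' analysed as a single full-length segment and flagged.
#'
#' @param traj A [trajectory()].
#' @param cfg A [welch_config()].
#' @return A list with elements `x` and `y`, each a `power_spectrum` with
#'   fields `frequencies` (Hz), `power` (mm^2/Hz), `axis`, `df`,
#'   `n_segments`, `full_length_fallback`.
#' @export
welch_psd <- function(traj, cfg = welch_config()) {
  stopifnot(inherits(traj, "bot_trajectory"), inherits(cfg, "welch_config"))
  out <- lapply(c(x = "x", y = "y"), function(ax) {
    ps <- welch_one(traj[[ax]], traj$sampling_rate, cfg)
    ps$axis <- ax
    class(ps) <- "power_spectrum"
    ps
  })
  out
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> axis %s: %d bins, df = %.4g Hz, %d segment(s)%s\n",
              x$axis, length(x$frequencies), x$df, x$n_segments,
              if (x$full_length_fallback) " [full-length fallback]" else ""))
  invisible(x)
}

#' Detect significant spectral peaks
#'
#' Peaks are strict local maxima of the power spectral density whose power
#' exceeds the detection threshold. The threshold is given in tracker units
#' (px^2/Hz) and converted to mm^2/Hz with the square of the pixel scale;
#' the default 10 px^2/Hz was calibrated to sit above the centre-of-mass
#' tracking noise floor. The zero-frequency bin is excluded, and maxima
#' within one frequency bin of each other are merged keeping the larger.
#'
#' @param ps A `power_spectrum` from [welch_psd()].
#' @param threshold_px2_per_hz Detection threshold in px^2/Hz (> 0).
#' @param pixel_scale Pixel scale in mm/px used for the conversion.
#' @return A `data.frame` of class `spectral_peaks` with columns `axis`,
#'   `frequency` (Hz), `power` (mm^2/Hz); zero rows when nothing crosses the
#'   threshold.
#' @export
detect_peaks <- function(ps, threshold_px2_per_hz = 10, pixel_scale = 0.13) {
  stopifnot(inherits(ps, "power_spectrum"))
  stop_if_not_scalar_number(threshold_px2_per_hz, "threshold_px2_per_hz", positive = TRUE)
  stop_if_not_scalar_number(pixel_scale, "pixel_scale", positive = TRUE)
  thr <- threshold_px2_per_hz * pixel_scale^2
  p <- ps$power; f <- ps$frequencies
  n <- length(p)
  peaks <- integer()
  if (n >= 3L) {
    i <- 2:(n - 1L)
    is_max <- p[i] > p[i - 1L] & p[i] > p[i + 1L] & p[i] > thr & f[i] > 0
    peaks <- i[is_max]
  }
  # merge maxima closer than or equal to one bin, keeping the larger
  if (length(peaks) > 1L) {
    keep <- rep(TRUE, length(peaks))
    for (k in 2:length(peaks)) {
      if (f[peaks[k]] - f[peaks[k - 1L]] <= ps$df * (1 + 1e-9)) {
        drop <- if (p[peaks[k]] >= p[peaks[k - 1L]]) k - 1L else k
        keep[drop] <- FALSE
      }
    }
    peaks <- peaks[keep]
  }
  structure(data.frame(axis = rep(ps$axis, length(peaks)),
                       frequency = f[peaks], power = p[peaks],
                       stringsAsFactors = FALSE),
            class = c("spectral_peaks", "data.frame"),
            df = ps$df, threshold_px2 = threshold_px2_per_hz,
            threshold_mm2 = thr)
}

#' Movement Complexity Index
#'
#' The Complexity Index (CI) is the number of unique significant peak
#' frequencies in the union of the x- and y-axis spectra: peaks on either
#' axis whose frequencies differ by at most `match_tol_hz` are counted once.
#' A constant-radius circular trajectory (one coincident peak per axis)
#' scores CI = 1; an immobile organoid scores CI = 0; spirograph-like paths
#' score higher.
#'
#' @param peaks_x,peaks_y `spectral_peaks` from [detect_peaks()] for the two
#'   axes.
#' @param match_tol_hz Frequency tolerance for identifying peaks across (and
#'   within) axes; default one Welch bin width.
#' @return A `complexity_result` with fields `peaks` (combined data.frame),
#'   `unique_frequencies`, `ci` (integer), `threshold_px2`, `threshold_mm2`,
#'   `match_tol_hz`.
#' @export
complexity_index <- function(peaks_x, peaks_y, match_tol_hz = NULL) {
  stopifnot(inherits(peaks_x, "spectral_peaks"), inherits(peaks_y, "spectral_peaks"))
  match_tol_hz <- match_tol_hz %||% attr(peaks_x, "df")
  all_peaks <- rbind(as.data.frame(peaks_x), as.data.frame(peaks_y))
  uniq <- numeric()
  if (nrow(all_peaks)) {
    f <- sort(all_peaks$frequency)
    # single-linkage clustering over the sorted frequencies: chains of gaps
    # <= tol collapse into one unique peak
    brk <- which(diff(f) > match_tol_hz * (1 + 1e-9))
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(f))
    uniq <- vapply(seq_along(starts),
                   function(i) mean(f[starts[i]:ends[i]]), numeric(1))
  }
  structure(list(peaks = all_peaks, unique_frequencies = uniq,
                 ci = length(uniq),
                 threshold_px2 = attr(peaks_x, "threshold_px2"),
                 threshold_mm2 = attr(peaks_x, "threshold_mm2"),
                 match_tol_hz = match_tol_hz),
            class = "complexity_result")
}

#' @export
print.complexity_result <- function(x, ...) {
  cat(sprintf("<complexity_result> CI = %d (%d x-peaks, %d y-peaks)\n",
              x$ci, sum(x$peaks$axis == "x"), sum(x$peaks$axis == "y")))
  if (x$ci)
    cat("  unique frequencies (Hz):",
        paste(signif(x$unique_frequencies, 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-call trajectory complexity pipeline
#'
#' Convenience wrapper: Welch spectra on both axes, peak detection, and the
#' Complexity Index, optionally followed by surrogate validation.
#'
#' @inheritParams detect_peaks
#' @param traj A [trajectory()].
#' @param cfg A [welch_config()].
#' @param surrogate Optional [surrogate_config()]; when supplied, each peak
#'   is validated against phase-randomized surrogates (see
#'   [surrogate_validate()]) and the validation table is attached.
#' @return A `complexity_result`; with validation, field `surrogate` holds
#'   the per-peak table.
#' @export
trajectory_complexity <- function(traj, cfg = welch_config(),
                                  threshold_px2_per_hz = 10,
                                  pixel_scale = traj$pixel_scale,
                                  surrogate = NULL) {
  ps <- welch_psd(traj, cfg)
  px <- detect_peaks(ps$x, threshold_px2_per_hz, pixel_scale)
  py <- detect_peaks(ps$y, threshold_px2_per_hz, pixel_scale)
  res <- complexity_index(px, py)
  if (!is.null(surrogate))
    res$surrogate <- surrogate_validate(traj, res, surrogate)
  res
}

#' Relative complexity under a treatment
#'
#' The treatment CI minus the mean CI across the consecutive control
#' recordings, so zero means "as complex as the average control".
#'
#' @param ci_treatment CI measured under treatment.
#' @param ci_controls Numeric vector of control CIs (>= 1 value).
#' @return `ci_treatment - mean(ci_controls)`.
#' @export
relative_complexity <- function(ci_treatment, ci_controls) {
  if (length(ci_controls) < 1L) stop("at least one control CI is required")
  stop_if_not_scalar_number(ci_treatment, "ci_treatment")
  ci_treatment - mean(ci_controls)
}
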