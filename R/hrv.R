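# Heart-rate-variability metrics from ECG waveforms and R-R interval series.

rr_intervals <- function(rr) {
  if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
}

#' Detect R-wave peaks in an ECG waveform
#'
#' Adaptive-threshold peak picking: a sample is accepted as an R peak when it
#' is a local maximum exceeding 0.6 times the rolling 2-second signal
#' maximum, subject to a 250 ms refractory period (physiologic upper bound of
#' ~240 bpm). Candidates inside the refractory window of an accepted peak are
#' discarded in favour of the earlier, already-accepted peak.
#'
#' Before thresholding, the waveform is smoothed with a short centred
#' moving average (roughly matched to the R-wave width) so that additive
#' wide-band noise does not displace the local maxima.
#'
#' @param samples numeric waveform (arbitrary units, R amplitude dominant).
#' @param fs sampling frequency, >= 100 Hz; at least 2 s of signal required.
#' @param threshold_frac fraction of the rolling maximum used as threshold.
#' @param refractory_ms minimum peak-to-peak gap, ms.
#' @param smooth_ms width of the centred moving-average pre-filter, ms
#'   (0 disables smoothing).
#' @return Numeric vector of strictly increasing peak times (ms). When no
#'   sample clears the adaptive threshold the result is empty and carries
#'   attribute `no_peaks = TRUE` with a warning.
#' @export
#' @examples
#' ecg <- simulate_ecg(c(800, 820, 790), fs = 250)
#' detect_r_peaks(ecg$mv, fs = 250)
detect_r_peaks <- function(samples, fs, threshold_frac = 0.6,
                           refractory_ms = 250, smooth_ms = 24) {
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  n <- length(samples)
  if (n < 2 * fs) stop("at least 2 s of signal is required", call. = FALSE)
  ks <- max(1L, as.integer(round(smooth_ms * fs / 1000)))
  if (ks %% 2L == 0L) ks <- ks + 1L
  if (ks > 1L) {
    samples <- as.numeric(stats::filter(samples, rep(1 / ks, ks), sides = 2L))
    half <- ks %/% 2L
    samples[seq_len(half)] <- samples[half + 1L]
    samples[(n - half + 1L):n] <- samples[n - half]
  }
  w <- as.integer(2 * fs)
  roll_max <- zoo::rollapply(zoo::zoo(samples), width = w, FUN = max,
                             partial = TRUE, align = "center")
  thr <- threshold_frac * as.numeric(roll_max)
  # local maxima above the adaptive threshold (plateaus take the first sample)
  left <- c(-Inf, samples[-n])
  right <- c(samples[-1L], -Inf)
  cand <- which(samples > thr & samples >= left & samples > right & samples > 0)
  if (!length(cand)) {
    warning("no sample exceeded the adaptive threshold; returning no peaks")
    return(structure(numeric(0), no_peaks = TRUE))
  }
  refr <- refractory_ms * fs / 1000
  keep <- cand[1L]
  for (i in cand[-1L]) {
    if (i - keep[length(keep)] >= refr) keep <- c(keep, i)
  }
  (keep - 1L) * 1000 / fs
}

#' Time-domain HRV metrics
#'
#' `compute_sdnn()` is the sample standard deviation (n - 1 denominator) of
#' the R-R intervals; `compute_cv()` is the SDNN divided by the mean R-R
#' interval. Larger values indicate a more responsive cardiac autonomic
#' state.
#'
#' @param rr an [rr_series()] or numeric vector of R-R intervals (ms).
#' @return SDNN in ms, or the dimensionless coefficient of variation.
#' @export
#' @examples
#' compute_sdnn(c(800, 810, 790, 805, 795)) # 7.9057
#' compute_cv(c(800, 810, 790, 805, 795))   # 0.009882
compute_sdnn <- function(rr) {
  x <- rr_intervals(rr)
  if (length(x) < 2L) stop("SDNN needs at least 2 intervals", call. = FALSE)
  stats::sd(x)
}

#' @rdname compute_sdnn
#' @export
compute_cv <- function(rr) {
  x <- rr_intervals(rr)
  if (length(x) < 2L) stop("CV needs at least 2 intervals", call. = FALSE)
  stats::sd(x) / mean(x)
}

# Welch averaged modified periodogram (Hann window, 50% overlap).
# Returns freq (Hz) and one-sided power spectral density.
welch_psd <- function(x, fs, nseg = min(256L, length(x))) {
  n <- length(x)
  nseg <- as.integer(min(nseg, n))
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * u)
    p <- sp[seq_len(nf + 1L)]
    # fold to one-sided (DC and, for even segment lengths, Nyquist unscaled)
    hi <- nf + (nseg %% 2L)
    if (hi >= 2L) p[2L:hi] <- 2 * p[2L:hi]
    acc <- acc + p
  }
  list(freq = (0:nf) * fs / nseg, psd = acc / length(starts))
}

#' Frequency-domain HRV: LF and HF power by Welch's method
#'
#' The R-R tachogram is interpolated to evenly spaced samples (cubic spline,
#' 4 Hz), the power spectral density is estimated by Welch's averaged
#' modified periodogram (Hann window, segments of `min(256, n)` samples, 50%
#' overlap), and power is integrated over the low-frequency band
#' (0.04-0.15 Hz, sympathetic dominance) and high-frequency band
#' (0.15-0.40 Hz, parasympathetic/respiratory dominance).
#'
#' @param rr an [rr_series()] or numeric vector of R-R intervals (ms);
#'   the record must span at least 120 s.
#' @param resample_hz interpolation rate (Hz).
#' @param lf_band,hf_band frequency bands (Hz).
#' @return List with `lf_power`, `hf_power` (ms^2), `ratio`, `freq`, `psd`.
#' @export
#' @examples
#' t <- cumsum(rep(0.8, 400))
#' rr <- 800 + 30 * sin(2 * pi * 0.10 * t)
#' compute_lf_hf(rr)$ratio
compute_lf_hf <- function(rr, resample_hz = 4,
                          lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40)) {
  x <- rr_intervals(rr)
  if (length(x) < 2L) stop("need at least 2 intervals", call. = FALSE)
  t_s <- cumsum(x) / 1000
  span <- t_s[length(t_s)] - t_s[1L]
  if (span < 120) {
    stop("R-R record must span at least 120 s for spectral analysis",
         call. = FALSE)
  }
  grid <- seq(t_s[1L], t_s[length(t_s)], by = 1 / resample_hz)
  xi <- stats::spline(t_s, x, xout = grid, method = "fmm")$y
  sp <- welch_psd(xi, fs = resample_hz)
  df <- sp$freq[2L] - sp$freq[1L]
  band_power <- function(band) {
    sum(sp$psd[sp$freq > band[1L] & sp$freq <= band[2L]]) * df
  }
  lf <- band_power(lf_band)
  hf <- band_power(hf_band)
  if (lf + hf < .Machine$double.eps * sum(sp$psd) || hf <= 0) {
    stop("insufficient variability in the LF/HF bands", call. = FALSE)
  }
  list(lf_power = lf, hf_power = hf, ratio = lf / hf,
       freq = sp$freq, psd = sp$psd)
}
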