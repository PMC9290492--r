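# FWHM-parameterised complex Morlet wavelet bank, log-power transform,
# trial-wise baseline correction and bootstrap significance of spectral
# modulations.

#' Build a Morlet wavelet bank parameterised by temporal FWHM
#'
#' Complex Morlet wavelets — complex sine waves tapered by a Gaussian — with
#' peak frequencies log-spaced between `f_lo` and `f_hi` and Gaussian-envelope
#' temporal FWHM log-spaced between `fwhm_lo_ms` and `fwhm_hi_ms` (decreasing
#' with frequency). Each kernel is
#' `exp(i*2*pi*f*t) * exp(-4*log(2)*t^2 / FWHM^2)`, sampled on
#' `t = -3*FWHM .. 3*FWHM` and normalised to unit energy so power is
#' comparable across frequencies.
#'
#' @param f_lo,f_hi Frequency endpoints (Hz); `f_hi` below Nyquist.
#' @param n Number of wavelets (>= 2).
#' @param fwhm_lo_ms,fwhm_hi_ms Temporal FWHM at `f_lo` / `f_hi` (ms).
#' @param fs Working sampling rate (Hz).
#'
#' @return A `pep_wavelet_bank`: list with `kernels` (complex vectors),
#'   `freqs_hz`, `fwhm_ms`, `half_lengths` (samples flagged edge-invalid at
#'   each end per kernel) and `fs`.
#' @export
build_wavelet_bank <- function(f_lo = 2, f_hi = 50, n = 30,
                               fwhm_lo_ms = 800, fwhm_hi_ms = 200, fs = 512) {
  if (n < 2) stop("need at least 2 wavelets")
  if (f_hi >= fs / 2) stop("f_hi must be below Nyquist")
  freqs <- exp(seq(log(f_lo), log(f_hi), length.out = n))
  fwhm_s <- exp(seq(log(fwhm_lo_ms), log(fwhm_hi_ms), length.out = n)) / 1000
  kernels <- vector("list", n)
  half_lengths <- integer(n)
  for (k in seq_len(n)) {
    hw <- ceiling(3 * fwhm_s[k] * fs)
    t <- (-hw:hw) / fs
    kern <- exp(1i * 2 * pi * freqs[k] * t) *
      exp(-4 * log(2) * t^2 / fwhm_s[k]^2)
    kernels[[k]] <- kern / sqrt(sum(Mod(kern)^2))
    half_lengths[k] <- hw
  }
  structure(list(kernels = kernels, freqs_hz = freqs,
                 fwhm_ms = fwhm_s * 1000, half_lengths = half_lengths,
                 fs = fs),
            class = "pep_wavelet_bank")
}

# FWHM of a sampled non-negative curve via interpolated half-maximum crossings
curve_fwhm <- function(x, axis) {
  pk <- which.max(x)
  half <- x[pk] / 2
  left <- which(x[seq_len(pk)] < half)
  right <- which(x[pk:length(x)] < half)
  if (length(left) == 0 || length(right) == 0) return(NA_real_)
  i <- max(left)                                  # last below-half on the left
  xl <- axis[i] + (half - x[i]) / (x[i + 1] - x[i]) * (axis[i + 1] - axis[i])
  j <- pk + min(right) - 1                        # first below-half on the right
  xr <- axis[j - 1] + (half - x[j - 1]) / (x[j] - x[j - 1]) *
    (axis[j] - axis[j - 1])
  xr - xl
}

#' Measure the temporal and spectral FWHM of each wavelet
#'
#' Empirical full-width at half-maximum of the amplitude envelope (temporal,
#' ms) and of the amplitude spectrum (spectral, Hz) of each kernel, by linear
#' interpolation of the half-maximum crossings.
#'
#' @param bank A `pep_wavelet_bank`.
#' @return Data frame with `freq_hz`, `fwhm_spec_ms`, `fwhm_measured_ms`,
#'   `fwhm_spectral_hz`.
#' @export
measure_wavelet_fwhm <- function(bank) {
  stopifnot(inherits(bank, "pep_wavelet_bank"))
  res <- lapply(seq_along(bank$kernels), function(k) {
    kern <- bank$kernels[[k]]
    n <- length(kern)
    t_ms <- (seq_len(n) - (n + 1) / 2) / bank$fs * 1000
    fwhm_t <- curve_fwhm(Mod(kern), t_ms)
    nfft <- 2^ceiling(log2(n * 8))
    spec <- Mod(stats::fft(c(kern, rep(0, nfft - n))))
    f_axis <- (seq_len(nfft) - 1) * bank$fs / nfft
    keep <- f_axis <= bank$fs / 2
    fwhm_f <- curve_fwhm(spec[keep], f_axis[keep])
    data.frame(freq_hz = bank$freqs_hz[k], fwhm_spec_ms = bank$fwhm_ms[k],
               fwhm_measured_ms = fwhm_t, fwhm_spectral_hz = fwhm_f)
  })
  do.call(rbind, res)
}

#' Wavelet transform of a single-trial signal
#'
#' Complex convolution of the signal with every kernel of the bank (FFT-based,
#' same-length output). Samples within half a kernel length of either end are
#' edge-invalid for that frequency and are excluded from baselines and
#' statistics downstream.
#'
#' @param x Numeric signal (longer than the longest kernel).
#' @param bank A `pep_wavelet_bank`.
#' @param times_s Optional time axis (seconds relative to the lock event),
#'   same length as `x`; carried into the map for baseline correction.
#'
#' @return A `pep_tfmap`: list with `values` (frequencies x time complex
#'   matrix), `kind = "complex"`, `freqs_hz`, `times_s`, `fs`,
#'   `half_lengths`, `baseline_window` (`NULL`).
#' @export
wavelet_transform <- function(x, bank, times_s = NULL) {
  stopifnot(inherits(bank, "pep_wavelet_bank"))
  n <- length(x)
  max_len <- max(lengths(bank$kernels))
  if (n <= max_len) stop("signal shorter than the longest kernel")
  if (!is.null(times_s) && length(times_s) != n)
    stop("times_s must match the signal length")
  nfft <- 2^ceiling(log2(n + max_len))
  Xf <- stats::fft(c(x, rep(0, nfft - n)))
  vals <- matrix(0i, nrow = length(bank$kernels), ncol = n)
  for (k in seq_along(bank$kernels)) {
    kern <- bank$kernels[[k]]
    Kf <- stats::fft(c(kern, rep(0, nfft - length(kern))))
    conv <- stats::fft(Xf * Kf, inverse = TRUE) / nfft
    off <- bank$half_lengths[k]              # centre of the odd-length kernel
    vals[k, ] <- conv[(off + 1):(off + n)]
  }
  structure(list(values = vals, kind = "complex", freqs_hz = bank$freqs_hz,
                 times_s = times_s, fs = bank$fs,
                 half_lengths = bank$half_lengths, baseline_window = NULL),
            class = "pep_tfmap")
}

#' Logarithmic power transform
#'
#' `10 * log10(|x|^2)`, floored at a small positive power to avoid `-Inf`.
#' Accepts real or complex values (the magnitude is used).
#'
#' @param x Coefficients or amplitudes.
#' @param floor Minimum power before the log (default `1e-12`).
#' @return Values in dB.
#' @export
log_power <- function(x, floor = 1e-12) {
  10 * log10(pmax(Mod(x)^2, floor))
}

#' Convert a complex time-frequency map to log power
#' @param tf A `pep_tfmap` with `kind = "complex"`.
#' @param floor Power floor (see [log_power()]).
#' @return The map with `values` in dB and `kind = "db"`.
#' @export
tf_log_power <- function(tf, floor = 1e-12) {
  stopifnot(inherits(tf, "pep_tfmap"))
  tf$values <- log_power(tf$values, floor)
  tf$kind <- "db"
  tf
}

# per-frequency edge-valid column range
tf_valid_range <- function(tf) {
  n <- ncol(tf$values)
  cbind(from = tf$half_lengths + 1, to = n - tf$half_lengths)
}

#' Trial-specific baseline correction of a log-power map
#'
#' Subtracts, per frequency, the mean log power over the baseline window from
#' the full time course. The window must lie inside the edge-valid region of
#' every frequency.
#'
#' @param tf A `pep_tfmap` in dB with a time axis.
#' @param window Baseline window in seconds relative to the lock event
#'   (default `c(-1.5, -0.5)`, relative to perturbation onset).
#' @return The baseline-corrected map (`baseline_window` recorded).
#' @export
baseline_correct <- function(tf, window = c(-1.5, -0.5)) {
  stopifnot(inherits(tf, "pep_tfmap"))
  if (tf$kind != "db") stop("baseline correction expects a log-power map")
  if (is.null(tf$times_s)) stop("map has no time axis")
  sel <- which(tf$times_s >= window[1] & tf$times_s <= window[2])
  if (length(sel) == 0) stop("baseline window outside the time axis")
  vr <- tf_valid_range(tf)
  if (any(sel[1] < vr[, "from"]) || any(sel[length(sel)] > vr[, "to"]))
    stop("baseline window overlaps edge-invalid samples")
  base <- rowMeans(tf$values[, sel, drop = FALSE])
  tf$values <- tf$values - base
  tf$baseline_window <- window
  tf
}

#' Bootstrap significance of across-trial mean modulations
#'
#' Percentile bootstrap confidence interval of the across-trial mean for every
#' bin; a bin is significant when its CI excludes 0 dB. Deterministic given
#' the seed.
#'
#' @param stack Trials x bins matrix, or a 3-d array with trials in the first
#'   dimension.
#' @param n_boot Number of bootstrap resamples (warns below 50).
#' @param alpha Two-sided significance level of the CI.
#' @param seed Integer seed.
#' @return List with `mean`, `ci_lo`, `ci_hi`, `mask` (each shaped like one
#'   bin slice of the input).
#' @export
bootstrap_significance <- function(stack, n_boot = 200, alpha = 0.05,
                                   seed = 1L) {
  dims <- dim(stack)
  if (is.null(dims) || length(dims) < 2) stop("stack must be trials x bins")
  if (dims[1] < 10) stop("need at least 10 trials")
  if (n_boot < 50) warning("fewer than 50 bootstrap resamples")
  bin_shape <- dims[-1]
  Y <- matrix(stack, nrow = dims[1])
  n_tr <- dims[1]
  set.seed(seed)
  counts <- matrix(0, nrow = n_boot, ncol = n_tr)
  for (b in seq_len(n_boot))
    counts[b, ] <- tabulate(sample.int(n_tr, replace = TRUE), nbins = n_tr)
  boot_means <- (counts %*% Y) / n_tr
  qs <- apply(boot_means, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  reshape_bin <- function(v) if (length(bin_shape) > 1) array(v, bin_shape) else v
  ci_lo <- qs[1, ]; ci_hi <- qs[2, ]
  list(mean = reshape_bin(colMeans(Y)),
       ci_lo = reshape_bin(ci_lo), ci_hi = reshape_bin(ci_hi),
       mask = reshape_bin(ci_lo > 0 | ci_hi < 0))
}
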