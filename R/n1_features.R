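# Single-trial N1 amplitude/latency extraction, per-participant outlier
# rejection, and N1-locked time / time-frequency parameter grids.

#' Detect the single-trial N1 peak
#'
#' A copy of the trial activation is low-pass filtered at `lp_hz` (order-5
#' Butterworth, zero-phase) and the N1 is taken as the most negative local
#' minimum with negative value within the search window after perturbation
#' onset. Trials without such a minimum are flagged invalid rather than
#' raising an error.
#'
#' @param x Activation time series covering the search window plus filter
#'   padding.
#' @param fs Sampling rate (Hz).
#' @param onset_sample 1-based sample index of perturbation onset within `x`.
#' @param search_ms Search window after onset, `(0, 300]` ms by default.
#' @param lp_hz Low-pass cutoff for the detection copy (Hz).
#'
#' @return List with `valid`, `amplitude` (filtered activation units, signed),
#'   `latency_ms` (from onset, floored to the sample grid) and `sample`
#'   (index into `x`).
#' @export
detect_n1 <- function(x, fs, onset_sample, search_ms = c(0, 300), lp_hz = 30) {
  n <- length(x)
  w0 <- onset_sample + max(1, round(search_ms[1] / 1000 * fs))
  w1 <- onset_sample + round(search_ms[2] / 1000 * fs)
  if (w1 + 1 > n || onset_sample < 2)
    stop("activation does not cover the search window")
  bf <- signal::butter(5, lp_hz / (fs / 2), type = "low")
  xf <- as.numeric(signal::filtfilt(bf, x))
  idx <- w0:w1
  is_min <- xf[idx] < 0 & xf[idx] <= xf[idx - 1] & xf[idx] <= xf[idx + 1]
  if (!any(is_min))
    return(list(valid = FALSE, amplitude = NA_real_, latency_ms = NA_real_,
                sample = NA_integer_))
  cand <- idx[is_min]
  best <- cand[which.min(xf[cand])]
  list(valid = TRUE, amplitude = xf[best],
       latency_ms = floor((best - onset_sample) / fs * 1000),
       sample = best)
}

#' Reject outlier trials per participant
#'
#' Single-pass rejection: within each participant, mean and SD of N1 amplitude
#' and latency are computed over all valid trials, and trials beyond
#' `sd_limit` SDs from the mean on either feature are flagged rejected. A
#' zero SD (identical features) rejects nothing.
#'
#' @param features Data frame with columns `participant_id`, `n1_amplitude`,
#'   `n1_latency_ms`, `valid`.
#' @param sd_limit Rejection threshold in SD units (default 3).
#' @return The data frame with logical `kept` and character `reject_reason`
#'   columns added (invalid trials are never kept).
#' @export
reject_outlier_trials <- function(features, sd_limit = 3) {
  stopifnot(all(c("participant_id", "n1_amplitude", "n1_latency_ms",
                  "valid") %in% names(features)))
  features$kept <- FALSE
  features$reject_reason <- NA_character_
  for (id in unique(features$participant_id)) {
    sel <- which(features$participant_id == id & features$valid)
    if (length(sel) < 5)
      warning(sprintf("participant %s has fewer than 5 valid trials", id))
    z <- function(v) {
      s <- stats::sd(v)
      if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    za <- z(features$n1_amplitude[sel])
    zl <- z(features$n1_latency_ms[sel])
    keep <- abs(za) <= sd_limit & abs(zl) <= sd_limit
    features$kept[sel] <- keep
    features$reject_reason[sel[!keep]] <-
      ifelse(abs(za[!keep]) > sd_limit, "amplitude_outlier", "latency_outlier")
  }
  features$reject_reason[!features$valid] <- "no_negative_peak"
  features
}

#' N1-locked time and time-frequency parameter grids for one trial
#'
#' Samples 101 log-power values on a 10-ms grid within +/-500 ms of the
#' trial-specific N1 latency: time-domain values from the 30-Hz low-pass copy
#' of the activation (the same signal in which the N1 is defined; switchable
#' to the raw activation), and time-frequency values from the
#' baseline-corrected log-power map by nearest-sample lookup. Trials whose
#' grid exceeds the signal or the edge-valid region of the map are flagged.
#'
#' @param x Activation segment.
#' @param fs Sampling rate (Hz).
#' @param onset_sample Perturbation-onset index within `x`.
#' @param n1_latency_ms Trial N1 latency (ms from onset).
#' @param tf Optional `pep_tfmap` in dB computed on `x` (baseline-corrected).
#' @param grid_ms Grid offsets relative to the N1 (ms).
#' @param lp_hz,use_filtered Low-pass cutoff and whether time-domain values
#'   come from the filtered copy.
#' @param floor Log-power floor.
#'
#' @return List with `valid`, `time_grid` (length 101, dB) and `tf_grid`
#'   (frequencies x 101, dB; `NULL` when `tf` is absent).
#' @export
n1_locked_grids <- function(x, fs, onset_sample, n1_latency_ms, tf = NULL,
                            grid_ms = seq(-500, 500, by = 10), lp_hz = 30,
                            use_filtered = TRUE, floor = 1e-12) {
  n1_sample <- onset_sample + round(n1_latency_ms / 1000 * fs)
  grid_samples <- n1_sample + round(grid_ms / 1000 * fs)
  if (min(grid_samples) < 1 || max(grid_samples) > length(x))
    return(list(valid = FALSE, time_grid = NULL, tf_grid = NULL))
  src <- x
  if (use_filtered) {
    bf <- signal::butter(5, lp_hz / (fs / 2), type = "low")
    src <- as.numeric(signal::filtfilt(bf, x))
  }
  time_grid <- log_power(src[grid_samples], floor)
  names(time_grid) <- grid_ms
  tf_grid <- NULL
  if (!is.null(tf)) {
    if (tf$kind != "db") stop("tf map must be in dB")
    vr <- tf_valid_range(tf)
    if (any(min(grid_samples) < vr[, "from"]) ||
        any(max(grid_samples) > vr[, "to"]))
      return(list(valid = FALSE, time_grid = NULL, tf_grid = NULL))
    tf_grid <- tf$values[, grid_samples, drop = FALSE]
    colnames(tf_grid) <- grid_ms
  }
  list(valid = TRUE, time_grid = time_grid, tf_grid = tf_grid)
}
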