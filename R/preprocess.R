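# Continuous-signal conditioning: band-pass filtering, anti-aliased
# downsampling, common-average referencing, null-space removal and epoching.

#' Band-pass filter a recording (zero phase)
#'
#' Order-5 Butterworth high-pass followed by an order-5 low-pass, each applied
#' forward and backward (zero phase shift; effective order 10). Length is
#' preserved.
#'
#' @param rec A [recording()].
#' @param lo,hi Band edges (Hz); `hi` must be below Nyquist.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 200) {
  stopifnot(inherits(rec, "pep_recording"))
  if (hi >= rec$fs / 2) stop("high cutoff must be below Nyquist")
  if (lo <= 0 || lo >= hi) stop("invalid band edges")
  bh <- signal::butter(5, lo / (rec$fs / 2), type = "high")
  bl <- signal::butter(5, hi / (rec$fs / 2), type = "low")
  out <- t(apply(rec$samples, 1, function(x)
    as.numeric(signal::filtfilt(bl, signal::filtfilt(bh, x)))))
  as_recording_like(rec, out)
}

#' Downsample a recording with anti-aliasing
#'
#' Zero-phase anti-aliased decimation to a lower rate: an order-8 Butterworth
#' low-pass at 80% of the target Nyquist frequency, applied forward and
#' backward, followed by sample selection. Event sample indices are rescaled
#' (and rounded) to the new rate. Upsampling is refused, as are non-integer
#' rate ratios.
#'
#' @param rec A [recording()].
#' @param target_fs Target rate (Hz), at most `rec$fs`; `fs / target_fs` must
#'   be an integer.
#' @return The resampled recording.
#' @export
resample_recording <- function(rec, target_fs = 512) {
  stopifnot(inherits(rec, "pep_recording"))
  if (target_fs > rec$fs) stop("upsampling not supported")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("only integer decimation factors are supported")
  q <- round(q)
  bf <- signal::butter(8, 0.8 / q, type = "low")
  keep <- seq(1, ncol(rec$samples), by = q)
  out <- t(apply(rec$samples, 1, function(x)
    as.numeric(signal::filtfilt(bf, x))[keep]))
  ev <- rec$events
  if (nrow(ev) > 0)
    ev$sample <- pmax(1L, as.integer(round((ev$sample - 1) *
                                             target_fs / rec$fs) + 1L))
  recording(out, target_fs, rec$channel_roles, ev)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over the included channels from each
#' included channel. By default all non-scalp (EOG) channels are excluded from
#' both the average and the re-referencing.
#'
#' @param rec A [recording()].
#' @param exclude Indices (or logical vector) of channels to leave untouched;
#'   defaults to channels whose role is not `"scalp"`.
#' @return The re-referenced recording.
#' @export
rereference_common_average <- function(rec, exclude = NULL) {
  stopifnot(inherits(rec, "pep_recording"))
  if (is.null(exclude)) exclude <- which(rec$channel_roles != "scalp")
  if (is.logical(exclude)) exclude <- which(exclude)
  include <- setdiff(seq_len(n_channels(rec)), exclude)
  if (length(include) < 2) stop("need at least 2 included channels")
  out <- rec$samples
  avg <- colMeans(out[include, , drop = FALSE])
  out[include, ] <- sweep(out[include, , drop = FALSE], 2, avg)
  as_recording_like(rec, out)
}

#' Automated bad-channel rejection
#'
#' Flags channels whose robust variance (squared MAD) exceeds `k` times the
#' median robust variance across scalp channels. This stands in for visual
#' identification of contaminated channels; the returned list of rejected
#' channels can be overridden by configuration.
#'
#' @param rec A [recording()].
#' @param k Multiplier on the median robust variance.
#' @return List with `recording` (bad channels removed) and `rejected`
#'   (indices into the input channel order).
#' @export
reject_bad_channels <- function(rec, k = 5) {
  stopifnot(inherits(rec, "pep_recording"))
  scalp <- which(rec$channel_roles == "scalp")
  rv <- apply(rec$samples[scalp, , drop = FALSE], 1, stats::mad)^2
  bad <- scalp[rv > k * stats::median(rv)]
  if (length(bad) > 0) {
    keep <- setdiff(seq_len(n_channels(rec)), bad)
    rec <- recording(rec$samples[keep, , drop = FALSE], rec$fs,
                     rec$channel_roles[keep], rec$events)
  }
  list(recording = rec, rejected = bad)
}

#' Remove the null-space principal component
#'
#' Common-average referencing makes the channel data rank-deficient; the
#' principal component with the smallest eigenvalue (the null space) is
#' removed before ICA. Returns the data expressed in the reduced
#' (channels - 1)-dimensional basis together with the back-projection matrix.
#'
#' @param rec A [recording()] (common-average referenced scalp channels).
#' @return List with `recording` (reduced basis, `channels - 1` rows),
#'   `backprojection` (channels x (channels - 1) orthonormal matrix),
#'   `eigenvalues` (all, descending) and `removed_eigenvalue`.
#' @export
remove_nullspace <- function(rec) {
  stopifnot(inherits(rec, "pep_recording"))
  X <- rec$samples
  if (ncol(X) < nrow(X)) stop("fewer samples than channels")
  cx <- X - rowMeans(X)
  eg <- eigen(tcrossprod(cx) / (ncol(X) - 1), symmetric = TRUE)
  keep <- seq_len(nrow(X) - 1)
  V <- eg$vectors[, keep, drop = FALSE]
  reduced <- crossprod(V, X)
  list(recording = recording(reduced, rec$fs,
                             rep("component", nrow(reduced)), rec$events),
       backprojection = V,
       eigenvalues = eg$values,
       removed_eigenvalue = eg$values[nrow(X)])
}

#' Segment a recording into event-locked epochs
#'
#' Cuts one epoch per perturbation-onset event. Events whose window falls
#' outside the recording are dropped with a warning.
#'
#' @param rec A [recording()] with events.
#' @param window_s Epoch window in seconds relative to onset (both endpoints
#'   included); default `c(-2, 9)`.
#' @return A `pep_epochs` object: list with `data` (trials x channels x time
#'   array), `times_s`, `fs`, `trial_ids`, `window_s`, `n_dropped`.
#' @export
epoch_recording <- function(rec, window_s = c(-2, 9)) {
  stopifnot(inherits(rec, "pep_recording"))
  if (nrow(rec$events) == 0) stop("recording has no events")
  o0 <- round(window_s[1] * rec$fs)
  o1 <- round(window_s[2] * rec$fs)
  idx_ok <- rec$events$sample + o0 >= 1 &
    rec$events$sample + o1 <= ncol(rec$samples)
  n_drop <- sum(!idx_ok)
  if (n_drop > 0)
    warning(sprintf("%d event(s) dropped: epoch window out of bounds", n_drop))
  ev <- rec$events[idx_ok, , drop = FALSE]
  if (nrow(ev) == 0) stop("no events fit the epoch window")
  n_t <- o1 - o0 + 1
  dat <- array(NA_real_, dim = c(nrow(ev), n_channels(rec), n_t))
  for (i in seq_len(nrow(ev))) {
    dat[i, , ] <- rec$samples[, (ev$sample[i] + o0):(ev$sample[i] + o1),
                              drop = FALSE]
  }
  structure(
    list(data = dat, times_s = (o0:o1) / rec$fs, fs = rec$fs,
         trial_ids = ev$trial_id, window_s = window_s, n_dropped = n_drop),
    class = "pep_epochs")
}

#' @export
print.pep_epochs <- function(x, ...) {
  cat(sprintf(
    "<pep_epochs> %d trial(s) x %d channel(s) x %d samples @ %g Hz, window [%g, %g] s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
    x$window_s[1], x$window_s[2]))
  invisible(x)
}
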