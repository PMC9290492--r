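#' Continuous multichannel recording
#'
#' Container for a continuous multichannel EEG/EOG-like signal with its
#' sampling rate, channel roles and perturbation-onset event markers. This is
#' the object passed between the generator, the preprocessing stages and the
#' source separation.
#'
#' @param samples Numeric matrix, channels x time. Row names (if any) are kept
#'   as channel labels.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_roles Character vector, one of `"scalp"` or `"eog"` per
#'   channel. Defaults to all `"scalp"`.
#' @param events Data frame with columns `sample` (1-based sample index of
#'   each perturbation onset, strictly increasing) and `trial_id`.
#'
#' @return An object of class `pep_recording`: a list with elements `samples`,
#'   `fs`, `channel_roles` and `events`.
#' @export
recording <- function(samples, fs, channel_roles = NULL, events = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.numeric(samples), length(fs) == 1, fs > 0)
  n_ch <- nrow(samples)
  if (is.null(channel_roles)) channel_roles <- rep("scalp", n_ch)
  if (length(channel_roles) != n_ch)
    stop("channel_roles must have one entry per channel")
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), trial_id = integer(0))
  }
  if (!all(c("sample", "trial_id") %in% names(events)))
    stop("events must have columns 'sample' and 'trial_id'")
  if (nrow(events) > 1 && any(diff(events$sample) <= 0))
    stop("event sample indices must be strictly increasing")
  if (nrow(events) > 0 &&
      (min(events$sample) < 1 || max(events$sample) > ncol(samples)))
    stop("event sample indices out of recording bounds")
  structure(
    list(samples = samples, fs = fs, channel_roles = channel_roles,
         events = events),
    class = "pep_recording")
}

#' @export
print.pep_recording <- function(x, ...) {
  cat(sprintf(
    "<pep_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %d event(s)\n",
    nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs,
    nrow(x$events)))
  invisible(x)
}

#' Number of channels / duration helpers
#' @param rec A `pep_recording`.
#' @return `n_channels()`: integer; `duration_s()`: seconds.
#' @export
n_channels <- function(rec) nrow(rec$samples)

#' @rdname n_channels
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

as_recording_like <- function(rec, samples, channel_roles = rec$channel_roles) {
  recording(samples, rec$fs, channel_roles, rec$events)
}
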