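# Source separation: infomax ICA on the null-space-reduced data and automated
# selection of the component carrying the perturbation-evoked N1.

#' Fit an ICA unmixing model
#'
#' Estimates a linear unmixing of the (null-space-reduced) channel data into
#' maximally independent component activations using symmetric FastICA with a
#' log-cosh contrast. Activations are scaled to unit variance with the scale
#' absorbed into the mixing weights. The decomposition is deterministic given
#' the seed.
#'
#' @param rec A [recording()] in the reduced basis (see [remove_nullspace()]).
#' @param seed Integer seed for the random rotation initialisation.
#' @param backprojection Optional channels x reduced matrix from
#'   [remove_nullspace()]; when given, component scalp maps are expressed on
#'   the original channels.
#' @param maxit,tol Iteration cap and convergence tolerance.
#'
#' @return A `pep_unmixing` model: list with `unmixing` (components x reduced
#'   channels), `mixing` (reduced channels x components), `scalp_maps`
#'   (channels x components), `center`, `n1_component` (`NA` until selected)
#'   and convergence info.
#' @export
fit_ica <- function(rec, seed = 1L, backprojection = NULL,
                    maxit = 500, tol = 1e-4) {
  stopifnot(inherits(rec, "pep_recording"))
  X <- t(rec$samples)
  nc <- ncol(X)
  set.seed(seed)
  fit <- ica::icafast(X, nc = nc, fun = "logcosh", maxit = maxit, tol = tol)
  if (!isTRUE(fit$converged))
    stop(sprintf("ICA did not converge after %d iteration(s); tol = %g",
                 fit$iter, tol))
  W <- fit$W                       # components x channels (reduced)
  M <- fit$M                       # channels (reduced) x components
  maps <- if (is.null(backprojection)) M else backprojection %*% M
  structure(
    list(unmixing = W, mixing = M, scalp_maps = maps,
         center = colMeans(X), n1_component = NA_integer_,
         iterations = fit$iter, vafs = fit$vafs, fs = rec$fs),
    class = "pep_unmixing")
}

#' @export
print.pep_unmixing <- function(x, ...) {
  cat(sprintf("<pep_unmixing> %d component(s), N1 component: %s (%d iterations)\n",
              nrow(x$unmixing),
              ifelse(is.na(x$n1_component), "not selected", x$n1_component),
              x$iterations))
  invisible(x)
}

#' Component activations of a recording
#'
#' Applies the unmixing weights (after removing the stored channel means) to
#' data in the same reduced basis the model was fitted on.
#'
#' @param model A `pep_unmixing` model.
#' @param rec A [recording()] in the reduced basis.
#' @return A [recording()] of component activations.
#' @export
component_activations <- function(model, rec) {
  stopifnot(inherits(model, "pep_unmixing"), inherits(rec, "pep_recording"))
  act <- model$unmixing %*% (rec$samples - model$center)
  recording(act, rec$fs, rep("component", nrow(act)), rec$events)
}

#' Automatically select the N1 component
#'
#' Replaces visual inspection with an automated criterion: for every
#' component, the trial-averaged activation (event-related potential) is
#' computed from onset-locked epochs; its largest-magnitude peak within
#' (0, 300] ms after onset — sign-flipped to negative, since ICA component
#' signs are arbitrary — is scaled by the RMS amplitude of the component's
#' back-projected scalp map. The component with the largest score wins.
#' Components whose post-onset trough does not exceed `min_ratio` times the
#' largest pre-onset ERP excursion are ineligible (a component without a
#' time-locked response has comparable extremes on both sides of the onset);
#' if none is eligible an error lists all scores.
#'
#' @param model A `pep_unmixing` model.
#' @param epochs A `pep_epochs` of component activations, time-locked to
#'   perturbation onset.
#' @param window_ms Post-onset search window (ms).
#' @param min_ratio Eligibility threshold: trough magnitude relative to the
#'   largest pre-onset ERP magnitude.
#'
#' @return The model with `n1_component` set. Attributes of the index carry
#'   the per-component `scores` and the sign convention (`signs`, applied so
#'   the N1-window peak of each component is negative); the model's unmixing,
#'   mixing and scalp-map entries for the selected component are sign-flipped
#'   accordingly.
#' @export
select_n1_component <- function(model, epochs, window_ms = c(0, 300),
                                min_ratio = 1.5) {
  stopifnot(inherits(model, "pep_unmixing"), inherits(epochs, "pep_epochs"))
  n_comp <- dim(epochs$data)[2]
  t_s <- epochs$times_s
  win <- t_s > window_ms[1] / 1000 & t_s <= window_ms[2] / 1000
  pre <- t_s < 0
  if (!any(win)) stop("epoch does not cover the selection window")
  scores <- numeric(n_comp)
  signs <- integer(n_comp)
  eligible <- logical(n_comp)
  for (k in seq_len(n_comp)) {
    erp <- colMeans(epochs$data[, k, , drop = FALSE][, 1, ])
    peak_i <- which.max(abs(erp[win]))
    peak <- erp[win][peak_i]
    signs[k] <- ifelse(peak > 0, -1L, 1L)       # flip so the peak is negative
    trough_mag <- abs(peak)
    scalp_rms <- sqrt(mean(model$scalp_maps[, k]^2))
    scores[k] <- trough_mag * scalp_rms
    eligible[k] <- trough_mag > min_ratio * max(abs(erp[pre]))
  }
  if (!any(eligible))
    stop("no component shows a reliable post-onset negative peak; scores: ",
         paste(sprintf("%.3g", scores), collapse = ", "))
  idx <- which.max(ifelse(eligible, scores, -Inf))
  if (signs[idx] < 0) {
    model$unmixing[idx, ] <- -model$unmixing[idx, ]
    model$mixing[, idx] <- -model$mixing[, idx]
    model$scalp_maps[, idx] <- -model$scalp_maps[, idx]
  }
  model$n1_component <- structure(idx, scores = scores, signs = signs,
                                  eligible = eligible)
  model
}
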