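# Group-level pooled single-trial regression of cortical parameters on
# perturbation intensity, stepping behaviour and their interaction, with
# Benjamini-Yekutieli FDR control over the time(-frequency) grid.

#' Participant-specific z-scoring
#'
#' Normalises a per-trial feature within each participant (subtract the
#' participant mean, divide by the participant SD, across all of that
#' participant's trials from both directions).
#'
#' @param values Per-trial feature values.
#' @param ids Participant id per trial.
#' @return Normalised values, same order.
#' @export
zscore_by_participant <- function(values, ids) {
  stopifnot(length(values) == length(ids))
  out <- numeric(length(values))
  for (id in unique(ids)) {
    sel <- ids == id
    if (sum(sel) < 2)
      stop(sprintf("participant %s has fewer than 2 trials", id))
    s <- stats::sd(values[sel])
    if (is.na(s) || s == 0)
      stop(sprintf("participant %s has zero-variance values", id))
    out[sel] <- (values[sel] - mean(values[sel])) / s
  }
  out
}

design_matrix <- function(design) {
  stopifnot(all(c("accel", "step") %in% names(design)))
  step <- as.numeric(design$step)
  if (!all(step %in% c(0, 1))) stop("step must be coded 0/1")
  X <- cbind(intercept = 1, accel = design$accel, step = step,
             accel_step = design$accel * step)
  if (length(unique(step)) < 2)
    stop("design rank-deficient: only one STEP level present ('step' column)")
  for (lv in c(0, 1))
    if (length(unique(design$accel[step == lv])) < 2)
      stop(sprintf(
        "design rank-deficient: fewer than 2 distinct ACCEL values at step = %d ('accel_step' column)",
        lv))
  X
}

#' Single-bin linear model of a cortical parameter
#'
#' Ordinary least squares for
#' `C ~ beta0 + beta1*ACCEL + beta2*STEP + beta3*ACCEL*STEP`, with two-tailed
#' t tests per coefficient, the overall model F test, adjusted R-squared and
#' 95% confidence intervals (a coefficient is nonzero when its CI excludes
#' zero).
#'
#' @param C Per-trial (normalised) cortical parameter.
#' @param design Data frame with `accel` (m/s^2, positive magnitude) and
#'   `step` (0 = non-stepping, 1 = stepping).
#' @return A `pep_glm_fit`: list with `coefficients` (data frame: estimate,
#'   se, t, p, ci_lo, ci_hi), `f`, `p_f`, `r2`, `adj_r2`, `df_resid`, `n`.
#' @export
fit_glm <- function(C, design) {
  X <- design_matrix(design)
  stopifnot(length(C) == nrow(X))
  fit <- stats::lm.fit(X, C)
  n <- length(C); p <- ncol(X)
  df_resid <- n - p
  rss <- sum(fit$residuals^2)
  tss <- sum((C - mean(C))^2)
  sigma2 <- rss / df_resid
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df_resid)
  tcrit <- stats::qt(0.975, df_resid)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / df_resid else NA_real_
  f <- if (tss > 0) ((tss - rss) / (p - 1)) / sigma2 else NA_real_
  p_f <- if (is.na(f)) NA_real_ else
    stats::pf(f, p - 1, df_resid, lower.tail = FALSE)
  structure(
    list(coefficients = data.frame(
           term = colnames(X), estimate = unname(fit$coefficients),
           se = se, t = unname(tval), p = unname(pval),
           ci_lo = unname(fit$coefficients - tcrit * se),
           ci_hi = unname(fit$coefficients + tcrit * se),
           row.names = NULL, stringsAsFactors = FALSE),
         f = f, p_f = p_f, r2 = r2, adj_r2 = adj_r2,
         df_resid = df_resid, n = n),
    class = "pep_glm_fit")
}

#' @export
print.pep_glm_fit <- function(x, ...) {
  cat(sprintf("<pep_glm_fit> n = %d, F(%d, %d) = %.2f (p = %.3g), adj R^2 = %.4f\n",
              x$n, 3, x$df_resid, x$f, x$p_f, x$adj_r2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Benjamini-Yekutieli FDR correction
#'
#' Step-up FDR control valid under arbitrary dependence, using the
#' harmonic-sum correction factor `c(m) = sum(1/i)`; adjusted p-values are
#' monotone non-decreasing in rank.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param alpha Significance level for the mask.
#' @param method `"BY"` (default) or any [stats::p.adjust()] method.
#' @return List with `p_adj` and logical `mask` (`p_adj <= alpha`).
#' @export
fdr_correct <- function(pvals, alpha = 0.01, method = "BY") {
  if (length(pvals) == 0)
    return(list(p_adj = numeric(0), mask = logical(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(pvals, method = method)
  list(p_adj = p_adj, mask = !is.na(p_adj) & p_adj <= alpha)
}

#' Mass-univariate regression over a parameter grid
#'
#' Fits the single-bin model of [fit_glm()] independently at every bin of a
#' time or time-frequency grid (vectorised over bins), then corrects the
#' p-values for false discovery rate per coefficient family across all bins of
#' the analysis (and the F-test p-values as their own family), emitting
#' significance masks at `alpha`. Degenerate bins (zero variance) yield `NA`
#' statistics and are reported, not fatal.
#'
#' @param Y Trials x bins matrix of (normalised) parameters.
#' @param design Data frame with `accel` and `step` (one row per trial).
#' @param alpha Significance level (default 0.01).
#' @param method FDR method (default `"BY"`).
#' @param bins Optional data frame of bin coordinates (one row per column of
#'   `Y`), carried into the result.
#'
#' @return A `pep_glm_grid`: list of 4 x bins matrices `beta`, `se`, `t`,
#'   `p`, `p_adj`, `mask`, plus per-bin vectors `f`, `p_f`, `p_f_adj`,
#'   `f_mask`, `r2`, `adj_r2`, and metadata (`alpha`, `method`, `df_resid`,
#'   `n`, `bins`, `failed_bins`, `fdr_family`).
#' @export
mass_univariate <- function(Y, design, alpha = 0.01, method = "BY",
                            bins = NULL) {
  Y <- as.matrix(Y)
  X <- design_matrix(design)
  stopifnot(nrow(Y) == nrow(X))
  n <- nrow(Y); p <- ncol(X); m <- ncol(Y)
  df_resid <- n - p
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, Y)                     # 4 x bins
  resid <- Y - X %*% B
  rss <- colSums(resid^2)
  tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
  sigma2 <- rss / df_resid
  se <- sqrt(outer(diag(xtx_inv), sigma2))             # 4 x bins
  tmat <- B / se
  pmat <- 2 * stats::pt(-abs(tmat), df_resid)
  ok <- tss > 0 & sigma2 > 0
  fvec <- ifelse(ok, ((tss - rss) / (p - 1)) / sigma2, NA_real_)
  p_f <- stats::pf(fvec, p - 1, df_resid, lower.tail = FALSE)
  r2 <- ifelse(ok, 1 - rss / tss, NA_real_)
  adj_r2 <- ifelse(ok, 1 - (1 - r2) * (n - 1) / df_resid, NA_real_)
  pmat[, !ok] <- NA_real_

  p_adj <- pmat
  mask <- matrix(FALSE, nrow = p, ncol = m)
  for (j in seq_len(p)) {
    fc <- fdr_correct(pmat[j, ], alpha, method)
    p_adj[j, ] <- fc$p_adj
    mask[j, ] <- fc$mask
  }
  fc_f <- fdr_correct(p_f, alpha, method)
  rn <- colnames(X)
  rownames(B) <- rownames(se) <- rownames(tmat) <- rownames(pmat) <-
    rownames(p_adj) <- rownames(mask) <- rn
  structure(
    list(beta = B, se = se, t = tmat, p = pmat, p_adj = p_adj, mask = mask,
         f = fvec, p_f = p_f, p_f_adj = fc_f$p_adj, f_mask = fc_f$mask,
         r2 = r2, adj_r2 = adj_r2, alpha = alpha, method = method,
         df_resid = df_resid, n = n, bins = bins,
         failed_bins = which(!ok),
         fdr_family = "per coefficient, across all bins of this analysis"),
    class = "pep_glm_grid")
}

#' @export
print.pep_glm_grid <- function(x, ...) {
  cat(sprintf(
    "<pep_glm_grid> %d bin(s), n = %d trials; %s-FDR at alpha = %g\n",
    ncol(x$beta), x$n, x$method, x$alpha))
  cat(sprintf("  significant bins per coefficient: %s\n",
              paste(sprintf("%s %d", rownames(x$mask), rowSums(x$mask)),
                    collapse = ", ")))
  best <- which.max(x$adj_r2)
  if (length(best) == 1)
    cat(sprintf("  best fit: bin %d, adj R^2 = %.4f, F = %.1f\n",
                best, x$adj_r2[best], x$f[best]))
  invisible(x)
}

#' Tidy per-bin results of a mass-univariate grid
#' @param grid A `pep_glm_grid`.
#' @return Data frame with one row per bin x coefficient.
#' @export
glm_grid_table <- function(grid) {
  stopifnot(inherits(grid, "pep_glm_grid"))
  m <- ncol(grid$beta)
  terms <- rownames(grid$beta)
  out <- data.frame(
    bin = rep(seq_len(m), each = length(terms)),
    term = rep(terms, times = m),
    estimate = as.numeric(grid$beta), se = as.numeric(grid$se),
    t = as.numeric(grid$t), p = as.numeric(grid$p),
    p_adj = as.numeric(grid$p_adj), significant = as.logical(grid$mask),
    stringsAsFactors = FALSE)
  if (!is.null(grid$bins))
    out <- cbind(out, grid$bins[out$bin, , drop = FALSE], row.names = NULL)
  out
}

#' Regression of the N1 latency on intensity and stepping
#'
#' Same model and inference as [fit_glm()], applied to the
#' participant-normalised single-trial N1 latency.
#'
#' @param latencies Normalised per-trial N1 latencies.
#' @param design Data frame with `accel` and `step`.
#' @return A `pep_glm_fit`.
#' @export
n1_latency_regression <- function(latencies, design) {
  fit_glm(latencies, design)
}
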