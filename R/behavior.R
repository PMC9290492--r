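# Reactive-step detection from vertical ground reaction forces and the
# behavioural statistics battery (stepping proportions, latency comparisons,
# logistic stepping-probability models).

#' Detect a reactive step from two vertical force traces
#'
#' Each trace is low-pass filtered at 20 Hz (order-5 Butterworth, applied
#' forward and backward for zero phase shift) and compared against a force
#' threshold. The first sample within the detection window at which either
#' filtered trace drops below the threshold defines foot-off; if neither trace
#' crosses within the window the trial is classified as a non-stepping
#' (feet-in-place) response. A simultaneous crossing of both feet is broken in
#' favour of the left foot.
#'
#' @param left_fz,right_fz Vertical ground-reaction-force traces (N).
#' @param fs Sampling rate of the traces (Hz).
#' @param onset_sample 1-based sample index of perturbation onset.
#' @param threshold_N Unloading threshold (N); ~1 kg.
#' @param window_ms Detection window after onset (ms).
#'
#' @return A `pep_step_event`: list with `stepped`, `foot_off_latency_ms`
#'   (`NA` when not stepped; computed as `floor(samples / fs * 1000)`) and
#'   `foot` (`"left"`/`"right"`/`NA`).
#' @export
detect_step <- function(left_fz, right_fz, fs, onset_sample,
                        threshold_N = 10, window_ms = 1000) {
  stopifnot(length(left_fz) == length(right_fz))
  win_n <- round(window_ms / 1000 * fs)
  if (onset_sample + win_n > length(left_fz))
    stop("detection window exceeds trace length")
  bf <- signal::butter(5, 20 / (fs / 2), type = "low")
  lf <- as.numeric(signal::filtfilt(bf, left_fz))
  rf <- as.numeric(signal::filtfilt(bf, right_fz))
  idx <- (onset_sample + 1):(onset_sample + win_n)
  first_below <- function(x) {
    hit <- which(x[idx] < threshold_N)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  l_hit <- first_below(lf)
  r_hit <- first_below(rf)
  if (is.na(l_hit) && is.na(r_hit)) {
    ev <- list(stepped = FALSE, foot_off_latency_ms = NA_real_,
               foot = NA_character_)
  } else {
    l <- ifelse(is.na(l_hit), Inf, l_hit)
    r <- ifelse(is.na(r_hit), Inf, r_hit)
    foot <- if (l <= r) "left" else "right"   # tie -> left
    hit <- min(l, r)
    ev <- list(stepped = TRUE,
               foot_off_latency_ms = floor(hit / fs * 1000),
               foot = foot)
  }
  structure(ev, class = "pep_step_event")
}

#' Fit the logistic stepping-probability model for one direction
#'
#' Maximum-likelihood logistic regression of the stepping outcome on
#' acceleration, with derived accelerations at 25/50/75% stepping probability
#' (`a_p = (logit(p) - intercept) / slope`). Complete separation is flagged
#' (with a warning) rather than raised as an error; the boundary estimate is
#' returned.
#'
#' @param trials Trial table with `direction`, `acceleration`, `stepped`.
#' @param direction `"backward"` or `"forward"`.
#'
#' @return A `pep_step_model`: list with `intercept`, `slope`, `a25`, `a50`,
#'   `a75`, `separation` flag, `n` and the underlying `glm` fit.
#' @export
fit_step_probability <- function(trials, direction) {
  d <- trials[trials$direction == direction, ]
  if (nrow(d) == 0) stop("no trials in requested direction")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(stepped ~ acceleration, family = stats::binomial(), data = d),
    warning = function(w) {
      sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- stats::coef(fit)
  degenerate <- length(unique(d$stepped)) < 2
  separation <- sep_warn || degenerate || abs(cf[2]) > 1e3
  if (separation)
    warning("separation (or near-separation) in stepping-probability fit; ",
            "boundary estimates returned")
  a_at <- function(p) unname((stats::qlogis(p) - cf[1]) / cf[2])
  structure(
    list(intercept = unname(cf[1]), slope = unname(cf[2]),
         a25 = a_at(0.25), a50 = a_at(0.5), a75 = a_at(0.75),
         separation = separation, n = nrow(d), fit = fit,
         direction = direction),
    class = "pep_step_model")
}

#' @export
print.pep_step_model <- function(x, ...) {
  cat(sprintf(
    "<pep_step_model> %s: a50 = %.3f m/s^2 (a25 %.3f, a75 %.3f), slope = %.2f, n = %d%s\n",
    x$direction, x$a50, x$a25, x$a75, x$slope, x$n,
    if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' Predict stepping probability from a fitted model
#' @param model A `pep_step_model`.
#' @param accel Accelerations (m/s^2).
#' @return Predicted probabilities.
#' @export
predict_step_probability <- function(model, accel) {
  stats::plogis(model$intercept + model$slope * accel)
}

#' Pearson chi-square on the direction x response 2x2 table
#'
#' One-degree-of-freedom Pearson chi-square without continuity correction on
#' the table of stepping / non-stepping counts by direction.
#'
#' @param step_b,nonstep_b,step_f,nonstep_f Pooled trial counts.
#' @return List with `chi2`, `df`, `p`.
#' @export
contingency_chi_square <- function(step_b, nonstep_b, step_f, nonstep_f) {
  counts <- c(step_b, nonstep_b, step_f, nonstep_f)
  if (any(counts < 0)) stop("counts must be non-negative")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Two-tailed paired t test on per-participant values
#'
#' One-sample t test on the differences `x - y` with `n - 1` degrees of
#' freedom. A zero-variance difference with nonzero mean is reported as
#' `t = +/-Inf` with a `degenerate` flag instead of an error.
#'
#' @param x,y Paired per-participant values (equal length >= 2, no missing).
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0)
      return(list(t = 0, df = length(d) - 1, p = 1, mean_diff = 0,
                  degenerate = TRUE))
    return(list(t = sign(mean(d)) * Inf, df = length(d) - 1, p = 0,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Trial-count-weighted pooled mean
#'
#' Pooled latency rows are weighted means of participant means with trial
#' counts as weights: `sum(count * mean) / sum(count)`.
#'
#' @param means Per-participant mean values.
#' @param counts Per-participant trial counts (> 0).
#' @return The pooled mean.
#' @export
pooled_weighted_mean <- function(means, counts) {
  if (length(means) != length(counts)) stop("length mismatch")
  if (any(counts <= 0)) stop("counts must be positive")
  sum(counts * means) / sum(counts)
}

#' Kolmogorov-Smirnov test against a continuous uniform distribution
#'
#' One-sample KS statistic of the trial accelerations against the uniform
#' distribution on `[range_lo, range_hi]`, with the asymptotic p-value
#' (appropriate at the several-hundred-trial scale of a session; ties from the
#' discrete acceleration grid are accepted).
#'
#' @param accels Trial accelerations (m/s^2); must lie within the range.
#' @param range_lo,range_hi Support of the uniform reference.
#' @return List with `D`, `p`, `n`.
#' @export
ks_uniformity <- function(accels, range_lo, range_hi) {
  if (range_lo >= range_hi) stop("range_lo must be below range_hi")
  if (length(accels) < 1) stop("need at least one value")
  if (any(accels < range_lo | accels > range_hi))
    stop("values outside the stated range")
  kt <- suppressWarnings(
    stats::ks.test(accels, "punif", range_lo, range_hi, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(accels))
}

#' Packaged per-participant summary tables
#'
#' Reads the packaged reference summaries of an 11-participant balance study:
#' `table1` holds trial counts and mean foot-off latencies (ms) per direction
#' and response type, `table2` the mean N1 latencies (ms) per condition.
#'
#' @return List with data frames `table1` and `table2`.
#' @export
load_summary_tables <- function() {
  p1 <- system.file("extdata", "table1.csv", package = "pepstep")
  p2 <- system.file("extdata", "table2.csv", package = "pepstep")
  list(table1 = utils::read.csv(p1, stringsAsFactors = FALSE),
       table2 = utils::read.csv(p2, stringsAsFactors = FALSE))
}

#' Build summary tables from trial-level data
#'
#' Aggregates a trial table (with stepping outcomes and optionally per-trial
#' N1 latencies) into the per-participant x direction x response-type shape of
#' the packaged summary tables, so the same statistics battery can run on
#' synthetic or laboratory data.
#'
#' @param trials Trial table with `participant_id`, `direction`, `stepped`,
#'   `foot_off_latency_ms`.
#' @param n1_latency_ms Optional per-trial N1 latencies aligned with `trials`.
#' @return List with `table1` and (if latencies given) `table2`.
#' @export
summarize_trials <- function(trials, n1_latency_ms = NULL) {
  ids <- sort(unique(trials$participant_id))
  agg <- function(id, dir, fun) {
    sel <- trials$participant_id == id & trials$direction == dir
    list(step = sum(sel & trials$stepped),
         nonstep = sum(sel & !trials$stepped),
         foot_off = mean(trials$foot_off_latency_ms[sel & trials$stepped]))
  }
  t1 <- do.call(rbind, lapply(ids, function(id) {
    b <- agg(id, "backward"); f <- agg(id, "forward")
    data.frame(participant = id,
               steps_backward = b$step, foot_off_backward_ms = b$foot_off,
               nonsteps_backward = b$nonstep,
               steps_forward = f$step, foot_off_forward_ms = f$foot_off,
               nonsteps_forward = f$nonstep, stringsAsFactors = FALSE)
  }))
  out <- list(table1 = t1)
  if (!is.null(n1_latency_ms)) {
    m <- function(id, dir, stepped) {
      sel <- trials$participant_id == id & trials$direction == dir &
        trials$stepped == stepped
      mean(n1_latency_ms[sel], na.rm = TRUE)
    }
    out$table2 <- do.call(rbind, lapply(ids, function(id) {
      data.frame(participant = id,
                 n1_step_backward_ms = m(id, "backward", TRUE),
                 n1_nonstep_backward_ms = m(id, "backward", FALSE),
                 n1_step_forward_ms = m(id, "forward", TRUE),
                 n1_nonstep_forward_ms = m(id, "forward", FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Behavioural statistics battery
#'
#' Computes, from per-participant summary tables, the full set of group-level
#' behavioural statistics: pooled trial counts and stepping proportions per
#' direction, the 2x2 chi-square for direction differences in stepping
#' proportion, paired t tests (trial counts between directions, foot-off
#' latency between directions, N1 latency stepping vs non-stepping per
#' direction, N1 vs foot-off latency per direction), mean N1-to-foot-off
#' latency differences with their ranges, and trial-count-weighted pooled
#' latency means.
#'
#' @param table1 Data frame shaped like the packaged `table1` (counts and
#'   foot-off latencies).
#' @param table2 Data frame shaped like the packaged `table2` (N1 latencies);
#'   optional — N1-based statistics are skipped when absent.
#' @return A `pep_behavioral_report` (list of statistics; see Details in the
#'   package vignette).
#' @export
behavioral_report <- function(table1, table2 = NULL) {
  t1 <- table1
  # paired tests need at least two participants; emit NULL otherwise
  safe_t <- function(x, y) if (length(x) >= 2) paired_t_test(x, y) else NULL
  counts <- list(
    step_b = sum(t1$steps_backward), nonstep_b = sum(t1$nonsteps_backward),
    step_f = sum(t1$steps_forward), nonstep_f = sum(t1$nonsteps_forward))
  total_b <- counts$step_b + counts$nonstep_b
  total_f <- counts$step_f + counts$nonstep_f
  rep <- list(
    counts = counts,
    n_backward = total_b, n_forward = total_f,
    prop_step_backward = 100 * counts$step_b / total_b,
    prop_step_forward = 100 * counts$step_f / total_f,
    chi_square = contingency_chi_square(counts$step_b, counts$nonstep_b,
                                        counts$step_f, counts$nonstep_f),
    t_counts = safe_t(t1$steps_backward + t1$nonsteps_backward,
                      t1$steps_forward + t1$nonsteps_forward),
    t_foot_off_direction = safe_t(t1$foot_off_backward_ms,
                                  t1$foot_off_forward_ms),
    pooled_foot_off_backward_ms = pooled_weighted_mean(
      t1$foot_off_backward_ms, t1$steps_backward),
    pooled_foot_off_forward_ms = pooled_weighted_mean(
      t1$foot_off_forward_ms, t1$steps_forward))
  if (!is.null(table2)) {
    t2 <- table2
    rep$t_n1_backward <- safe_t(t2$n1_step_backward_ms,
                                t2$n1_nonstep_backward_ms)
    rep$t_n1_forward <- safe_t(t2$n1_step_forward_ms,
                               t2$n1_nonstep_forward_ms)
    rep$t_n1_vs_foot_off_backward <- safe_t(t2$n1_step_backward_ms,
                                            t1$foot_off_backward_ms)
    rep$t_n1_vs_foot_off_forward <- safe_t(t2$n1_step_forward_ms,
                                           t1$foot_off_forward_ms)
    db <- t1$foot_off_backward_ms - t2$n1_step_backward_ms
    df_ <- t1$foot_off_forward_ms - t2$n1_step_forward_ms
    rep$n1_to_foot_off_backward <- list(mean = mean(db), range = range(db))
    rep$n1_to_foot_off_forward <- list(mean = mean(df_), range = range(df_))
    rep$pooled_n1_ms <- c(
      step_backward = pooled_weighted_mean(t2$n1_step_backward_ms,
                                           t1$steps_backward),
      nonstep_backward = pooled_weighted_mean(t2$n1_nonstep_backward_ms,
                                              t1$nonsteps_backward),
      step_forward = pooled_weighted_mean(t2$n1_step_forward_ms,
                                          t1$steps_forward),
      nonstep_forward = pooled_weighted_mean(t2$n1_nonstep_forward_ms,
                                             t1$nonsteps_forward))
  }
  structure(rep, class = "pep_behavioral_report")
}

#' @export
print.pep_behavioral_report <- function(x, ...) {
  cat("<pep_behavioral_report>\n")
  cat(sprintf("  trials: backward %d (%.1f%% stepping), forward %d (%.1f%% stepping)\n",
              x$n_backward, x$prop_step_backward,
              x$n_forward, x$prop_step_forward))
  cat(sprintf("  chi-square (direction x response): chi2 = %.2f, p = %.3g\n",
              x$chi_square$chi2, x$chi_square$p))
  if (!is.null(x$t_counts))
    cat(sprintf("  paired t, trial counts b vs f: t(%d) = %.2f, p = %.3g\n",
                x$t_counts$df, x$t_counts$t, x$t_counts$p))
  if (!is.null(x$t_foot_off_direction))
    cat(sprintf("  paired t, foot-off b vs f:     t(%d) = %.2f, p = %.3g\n",
                x$t_foot_off_direction$df, x$t_foot_off_direction$t,
                x$t_foot_off_direction$p))
  if (!is.null(x$t_n1_backward)) {
    cat(sprintf("  paired t, N1 step vs non-step: backward t(%d) = %.2f; forward t(%d) = %.2f\n",
                x$t_n1_backward$df, x$t_n1_backward$t,
                x$t_n1_forward$df, x$t_n1_forward$t))
    cat(sprintf("  N1 -> foot-off: backward %.0f ms [%.0f, %.0f]; forward %.0f ms [%.0f, %.0f]\n",
                x$n1_to_foot_off_backward$mean,
                x$n1_to_foot_off_backward$range[1],
                x$n1_to_foot_off_backward$range[2],
                x$n1_to_foot_off_forward$mean,
                x$n1_to_foot_off_forward$range[1],
                x$n1_to_foot_off_forward$range[2]))
  }
  cat(sprintf("  pooled foot-off: backward %.1f ms, forward %.1f ms\n",
              x$pooled_foot_off_backward_ms, x$pooled_foot_off_forward_ms))
  invisible(x)
}
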