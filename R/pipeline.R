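# End-to-end orchestration: synthetic generation -> step detection ->
# preprocessing -> ICA -> N1 features -> time-frequency grids -> pooled
# mass-univariate regression, with a provenance record.

#' Pipeline configuration
#'
#' Assembles every stage parameter with the study defaults: 1-200 Hz
#' band-pass, 512 Hz working rate, common-average reference, null-space
#' removal before ICA, (0, 300] ms N1 search, 2-50 Hz / 800-200 ms wavelet
#' bank, (-1.5, -0.5) s baseline, 101-point +/-500 ms N1-locked grids, +/-3 SD
#' trial rejection and BY-FDR at alpha = 0.01. Round-trips losslessly through
#' YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param n_participants Number of simulated participants.
#' @param n_blocks Blocks of 20 trials per participant (7 blocks = 140
#'   trials).
#' @param truth A [ground_truth()] object.
#' @param seed Master seed for the run.
#' @param ... Overrides for any default listed below.
#' @return A named list of class `pep_config`.
#' @export
pipeline_config <- function(n_participants = 11, n_blocks = 7,
                            truth = ground_truth(), seed = 1L, ...) {
  cfg <- list(
    n_participants = n_participants, n_blocks = n_blocks, truth = truth,
    seed = as.integer(seed),
    fs_eeg = 512, fs_grf = 2000, bodyweight_N = 700, grf_noise_sd = 2,
    filter_lo = 1, filter_hi = 200, resample_fs = 512,
    epoch_window_s = c(-2, 9), select_window_s = c(-0.5, 0.5),
    bank = list(f_lo = 2, f_hi = 50, n = 30,
                fwhm_lo_ms = 800, fwhm_hi_ms = 200),
    baseline_window_s = c(-1.5, -0.5),
    grid_ms = seq(-500, 500, by = 10),
    n1_search_ms = c(0, 300), n1_lp_hz = 30,
    sd_limit = 3, alpha = 0.01, fdr_method = "BY",
    normalize = TRUE)
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "pep_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}

#' Write / read a pipeline configuration as YAML
#' @param cfg A `pep_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns the reconstructed `pep_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$truth <- unclass(x$truth)
  x$truth$mixing_matrix_roles <- attr(x$truth$mixing_matrix, "channel_roles")
  x$truth$mixing_matrix_dimnames <- dimnames(x$truth$mixing_matrix)
  x$truth$mixing_matrix <- unname(apply(x$truth$mixing_matrix, 1, as.numeric,
                                        simplify = FALSE))
  # yaml drops names on atomic vectors; store named vectors as maps
  for (nm in c("a50", "slope_k", "band_burst_gains", "source_noise_sd"))
    x$truth[[nm]] <- as.list(x$truth[[nm]])
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  mm <- do.call(rbind, x$truth$mixing_matrix)
  if (!is.null(x$truth$mixing_matrix_dimnames))
    dimnames(mm) <- x$truth$mixing_matrix_dimnames
  attr(mm, "channel_roles") <- x$truth$mixing_matrix_roles
  x$truth$mixing_matrix_roles <- NULL
  x$truth$mixing_matrix_dimnames <- NULL
  tr <- x$truth
  tr$mixing_matrix <- mm
  x$truth <- do.call(ground_truth, c(
    tr[setdiff(names(tr), c("a50", "slope_k", "band_burst_gains",
                            "source_noise_sd"))],
    list(a50 = unlist(tr$a50), slope_k = unlist(tr$slope_k),
         band_burst_gains = unlist(tr$band_burst_gains),
         source_noise_sd = unlist(tr$source_noise_sd))))
  cfg <- do.call(pipeline_config, x[c("n_participants", "n_blocks", "seed")])
  extra <- setdiff(names(x), c("n_participants", "n_blocks", "seed", "truth"))
  for (nm in extra) {
    v <- x[[nm]]
    cfg[[nm]] <- if (is.list(v)) v else unlist(v)
  }
  cfg$truth <- x$truth
  cfg
}

# run one simulated participant through behaviour, preprocessing, ICA and
# feature extraction; returns features + grids + diagnostics
process_participant <- function(pid, cfg, bank) {
  truth <- cfg$truth
  truth$seed <- substream_seed(cfg$seed, sprintf("participant%02d", pid))
  id <- sprintf("S%02d", pid)
  trials <- generate_trial_schedule(cfg$n_blocks, seed = truth$seed,
                                    participant_id = id)
  trials <- simulate_stepping(trials, truth)

  # behaviour: simulate force plates and detect steps from them
  det <- lapply(seq_len(nrow(trials)), function(i) {
    grf <- generate_grf(trials[i, ], fs = cfg$fs_grf,
                        bodyweight_N = cfg$bodyweight_N,
                        noise_sd = cfg$grf_noise_sd, seed = truth$seed)
    detect_step(grf$left, grf$right, grf$fs, grf$onset_sample)
  })
  trials$detected_step <- vapply(det, function(e) e$stepped, logical(1))
  trials$detected_foot_off_ms <-
    vapply(det, function(e) e$foot_off_latency_ms, numeric(1))

  rec <- generate_eeg(trials, truth, fs = cfg$fs_eeg)
  injected <- attr(rec, "injected")

  rec <- bandpass_filter(rec, cfg$filter_lo, cfg$filter_hi)
  if (rec$fs > cfg$resample_fs) rec <- resample_recording(rec, cfg$resample_fs)
  rec <- rereference_common_average(rec)
  cr <- reject_bad_channels(rec)
  rec <- cr$recording
  scalp <- which(rec$channel_roles == "scalp")
  rec_scalp <- recording(rec$samples[scalp, , drop = FALSE], rec$fs,
                         rec$channel_roles[scalp], rec$events)
  ns <- remove_nullspace(rec_scalp)
  model <- fit_ica(ns$recording, seed = substream_seed(truth$seed, "ica"),
                   backprojection = ns$backprojection)
  act0 <- component_activations(model, ns$recording)
  model <- select_n1_component(model,
                               epoch_recording(act0, cfg$select_window_s))
  act <- component_activations(model, ns$recording)
  x <- act$samples[model$n1_component, ]
  fs <- act$fs

  margin_s <- max(bank$half_lengths) / bank$fs
  pre_n <- round((abs(cfg$baseline_window_s[1]) + margin_s + 0.1) * fs)
  post_n <- round((cfg$n1_search_ms[2] / 1000 + max(cfg$grid_ms) / 1000 +
                     margin_s + 0.1) * fs)

  n_tr <- nrow(rec$events)
  feats <- data.frame(participant_id = id, trial_id = rec$events$trial_id,
                      n1_amplitude = NA_real_, n1_latency_ms = NA_real_,
                      valid = FALSE, stringsAsFactors = FALSE)
  time_grids <- matrix(NA_real_, n_tr, length(cfg$grid_ms))
  tf_grids <- array(NA_real_, c(n_tr, length(bank$freqs_hz),
                                length(cfg$grid_ms)))
  for (i in seq_len(n_tr)) {
    onset <- rec$events$sample[i]
    i0 <- onset - pre_n; i1 <- onset + post_n
    if (i0 < 1 || i1 > length(x)) next
    seg <- x[i0:i1]
    onset_rel <- pre_n + 1
    n1 <- detect_n1(seg, fs, onset_rel, cfg$n1_search_ms, cfg$n1_lp_hz)
    feats$valid[i] <- n1$valid
    if (!n1$valid) next
    feats$n1_amplitude[i] <- n1$amplitude
    feats$n1_latency_ms[i] <- n1$latency_ms
    times_rel <- (seq_along(seg) - onset_rel) / fs
    tf <- wavelet_transform(seg, bank, times_s = times_rel)
    tf <- baseline_correct(tf_log_power(tf), cfg$baseline_window_s)
    g <- n1_locked_grids(seg, fs, onset_rel, n1$latency_ms, tf = tf,
                         grid_ms = cfg$grid_ms, lp_hz = cfg$n1_lp_hz)
    if (!g$valid) { feats$valid[i] <- FALSE; next }
    time_grids[i, ] <- g$time_grid
    tf_grids[i, , ] <- g$tf_grid
  }
  feats <- reject_outlier_trials(feats, cfg$sd_limit)

  list(trials = trials, injected = injected, features = feats,
       time_grids = time_grids, tf_grids = tf_grids, model = model,
       rejected_channels = cr$rejected,
       truth_source = attr(rec, "sources"))
}

#' Run the full synthetic pipeline
#'
#' Generates `n_participants` simulated sessions and runs each through step
#' detection, EEG conditioning, ICA with automatic N1-component selection,
#' single-trial N1 and time-frequency feature extraction and trial rejection;
#' then pools kept trials across participants and fits the mass-univariate
#' model per direction in the time and time-frequency domains, plus the N1
#' latency regression and the behavioural statistics battery.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Print stage progress.
#'
#' @return A `pep_report`: list with `trials` (pooled, with detected steps),
#'   `behavioral` (statistics battery on detected behaviour),
#'   `step_models` (logistic fits per direction), `features` (pooled N1
#'   features), `glm` (per direction: `time`, `tf`, `latency`), `grid_axes`,
#'   `injected` (pooled generator truth per trial) and `provenance`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = interactive()) {
  stopifnot(inherits(cfg, "pep_config"))
  bank <- do.call(build_wavelet_bank, c(cfg$bank, list(fs = cfg$resample_fs)))
  parts <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    if (verbose) message(sprintf("participant %d/%d", p, cfg$n_participants))
    parts[[p]] <- process_participant(p, cfg, bank)
  }
  trials <- do.call(rbind, lapply(parts, `[[`, "trials"))
  injected <- do.call(rbind, lapply(seq_along(parts), function(i)
    cbind(participant_id = sprintf("S%02d", i), parts[[i]]$injected)))
  feats <- do.call(rbind, lapply(parts, `[[`, "features"))
  time_grids <- do.call(rbind, lapply(parts, `[[`, "time_grids"))
  tf_flat <- do.call(rbind, lapply(parts, function(pp) {
    d <- dim(pp$tf_grids)
    matrix(pp$tf_grids, nrow = d[1])
  }))

  # align trial metadata (direction, acceleration, detected behaviour)
  feats$direction <- trials$direction
  feats$accel <- trials$acceleration
  feats$step <- as.numeric(trials$detected_step)
  feats$n1_log_power <- log_power(feats$n1_amplitude)

  behav_tabs <- summarize_trials(data.frame(
    participant_id = trials$participant_id, direction = trials$direction,
    stepped = trials$detected_step,
    foot_off_latency_ms = trials$detected_foot_off_ms,
    stringsAsFactors = FALSE), feats$n1_latency_ms)
  behavioral <- behavioral_report(behav_tabs$table1, behav_tabs$table2)
  step_trials <- data.frame(direction = trials$direction,
                            acceleration = trials$acceleration,
                            stepped = trials$detected_step)
  step_models <- list(
    backward = fit_step_probability(step_trials, "backward"),
    forward = fit_step_probability(step_trials, "forward"))

  kept <- feats$kept
  norm_or_raw <- function(v) {
    if (cfg$normalize) zscore_by_participant(v[kept], feats$participant_id[kept])
    else v[kept]
  }
  norm_cols <- function(M) {
    M <- M[kept, , drop = FALSE]
    if (!cfg$normalize) return(M)
    for (j in seq_len(ncol(M)))
      M[, j] <- zscore_by_participant(M[, j], feats$participant_id[kept])
    M
  }
  Yt <- norm_cols(time_grids)
  Ytf <- norm_cols(tf_flat)
  lat_norm <- norm_or_raw(feats$n1_latency_ms)
  fk <- feats[kept, ]

  tf_bins <- expand.grid(freq_hz = bank$freqs_hz, time_ms = cfg$grid_ms)
  time_bins <- data.frame(time_ms = cfg$grid_ms)
  glm_res <- lapply(c(backward = "backward", forward = "forward"),
                    function(d) {
    sel <- fk$direction == d
    design <- data.frame(accel = fk$accel[sel], step = fk$step[sel])
    list(time = mass_univariate(Yt[sel, , drop = FALSE], design,
                                alpha = cfg$alpha, method = cfg$fdr_method,
                                bins = time_bins),
         tf = mass_univariate(Ytf[sel, , drop = FALSE], design,
                              alpha = cfg$alpha, method = cfg$fdr_method,
                              bins = tf_bins),
         latency = n1_latency_regression(lat_norm[sel], design))
  })

  structure(
    list(trials = trials, behavioral = behavioral, step_models = step_models,
         features = feats, glm = glm_res,
         grid_axes = list(time_ms = cfg$grid_ms, freqs_hz = bank$freqs_hz),
         time_grids = time_grids, tf_grids = tf_flat, injected = injected,
         provenance = list(config_hash = config_hash(cfg), seed = cfg$seed,
                           package_version =
                             as.character(utils::packageVersion("pepstep")),
                           timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pep_report")
}

#' @export
print.pep_report <- function(x, ...) {
  cat(sprintf("<pep_report> %d trial(s), %d participant(s) [config %s]\n",
              nrow(x$trials), length(unique(x$trials$participant_id)),
              x$provenance$config_hash))
  print(x$behavioral)
  for (d in names(x$glm)) {
    g <- x$glm[[d]]$tf
    cat(sprintf("  %s TF grid: best adj R^2 = %.3f; significant accel bins: %d/%d\n",
                d, max(g$adj_r2, na.rm = TRUE), sum(g$mask["accel", ]),
                ncol(g$mask)))
  }
  invisible(x)
}

#' Write the tidy per-stage outputs of a report
#'
#' Emits `trials.csv`, `features.csv`, per-direction GLM grid tables and a
#' `provenance.json`-style YAML record into a directory.
#'
#' @param report A `pep_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pep_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  for (d in names(report$glm)) {
    utils::write.csv(glm_grid_table(report$glm[[d]]$tf),
                     file.path(dir, sprintf("glm_tf_%s.csv", d)),
                     row.names = FALSE)
    utils::write.csv(glm_grid_table(report$glm[[d]]$time),
                     file.path(dir, sprintf("glm_time_%s.csv", d)),
                     row.names = FALSE)
  }
  yaml::write_yaml(report$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
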