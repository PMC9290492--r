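# Synthetic balance-perturbation data with known ground truth.
#
# The generator emulates the statistical structure of a platform-translation
# balance experiment: a randomized schedule of 20 acceleration levels in two
# sway directions, a logistic acceleration -> stepping law, two-plate vertical
# ground reaction forces with foot unloading on stepping trials, and
# multichannel EEG in which a midfrontal source emits an N1-shaped deflection
# and band-limited bursts whose log power follows a configurable linear model
# in acceleration, stepping and their interaction.

#' The standard acceleration set
#'
#' Twenty platform accelerations from 0.125 to 2.5 m/s^2 in steps of
#' 0.125 m/s^2.
#' @return Numeric vector of length 20 (m/s^2).
#' @export
default_accelerations <- function() seq(0.125, 2.5, by = 0.125)

# Deterministic per-stage seed derived from one master seed, so schedule,
# behaviour, GRF and EEG randomness are independent named substreams.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483647)
}

band_definitions <- function() {
  data.frame(band = c("theta", "alpha", "beta", "gamma"),
             freq_hz = c(4, 10, 20, 40),
             sd_s = c(0.12, 0.08, 0.06, 0.05),
             stringsAsFactors = FALSE)
}

#' Default forward-mixing matrix for the synthetic sources
#'
#' Abstract projection weights (not forward-modelled through a head model) for
#' three sources -- a midfrontal dipolar source, a frontal blink source and a
#' temporal broadband-muscle source -- onto 8 scalp channels plus 2 EOG
#' channels dominated by the blink source.
#'
#' @return A channels x sources numeric matrix with full column rank and a
#'   `channel_roles` attribute.
#' @export
default_mixing_matrix <- function() {
  m <- rbind(
    # scalp: midfrontal gradient, frontal blink leakage, temporal muscle
    c(1.00, 0.60, 0.05),
    c(0.90, 0.35, 0.10),
    c(0.70, 0.15, 0.45),
    c(0.50, 0.08, 0.15),
    c(0.30, 0.05, 0.05),
    c(0.15, 0.02, 0.80),
    c(0.05, 0.01, 0.30),
    c(-0.10, 0.00, 0.10),
    # EOG channels
    c(0.05, 1.20, 0.02),
    c(0.02, 1.00, 0.05))
  colnames(m) <- c("midfrontal", "blink", "muscle")
  rownames(m) <- c(paste0("EEG", 1:8), "EOG1", "EOG2")
  attr(m, "channel_roles") <- c(rep("scalp", 8), rep("eog", 2))
  m
}

#' Ground truth for the synthetic generator
#'
#' Collects every effect size, latency law, behavioural law and noise level the
#' generator injects, so that downstream recovery can be checked against known
#' values. Effects `beta0..beta3` act on the normalised log-power (dB) scale of
#' the model `E = beta0 + beta1*ACCEL + beta2*STEP + beta3*ACCEL*STEP`.
#'
#' Defaults: the stepping law reproduces group-level 50% stepping-probability
#' accelerations of 1.02 (backward) and 1.28 m/s^2 (forward) with logistic
#' steepness calibrated to 25/75% points at [0.87, 1.18] and [1.10, 1.46]
#' m/s^2 (k = log(3) / half-width). The N1 latency decreases with acceleration
#' and is shorter on stepping trials, mirroring the ordering seen in
#' perturbation studies.
#'
#' @param beta0,beta1,beta2,beta3 Effect sizes (dB) for intercept,
#'   acceleration, stepping and their interaction.
#' @param a50 Named vector: acceleration of 50% stepping probability (m/s^2)
#'   per direction (`backward`, `forward`).
#' @param slope_k Named vector: logistic steepness (per m/s^2) per direction.
#' @param n1_latency_base_ms Latency intercept of the N1 trough (ms).
#' @param n1_latency_accel_slope_ms Latency decrease per m/s^2 (ms).
#' @param n1_latency_step_ms Additive latency shift on stepping trials (ms).
#' @param n1_latency_jitter_ms Trial-to-trial latency jitter SD (ms).
#' @param n1_amp_base Baseline N1 trough amplitude (signal units at E = 0 dB).
#' @param burst_amp_base Baseline band-burst amplitude (signal units).
#' @param band_burst_gains Named amplitude multipliers per band
#'   (theta/alpha/beta/gamma); a gain of 0 disables the band.
#' @param amp_noise_sd Trial-level noise SD (dB) added to each injected E.
#' @param foot_off_base_ms,foot_off_accel_slope_ms,foot_off_sd_ms Affine
#'   decreasing mean model and SD for the foot-off latency, truncated to
#'   (150, 1000) ms.
#' @param mixing_matrix Channels x sources projection (full column rank).
#' @param source_noise_sd Named background noise SDs for the midfrontal (1/f),
#'   blink and muscle sources.
#' @param sensor_noise_sd Per-channel white sensor noise SD.
#' @param seed Master seed; all generator randomness flows from it via named
#'   substreams.
#'
#' @return An object of class `pep_ground_truth` (a validated list).
#' @export
ground_truth <- function(beta0 = 0, beta1 = 4, beta2 = 2, beta3 = -3,
                         a50 = c(backward = 1.02, forward = 1.28),
                         slope_k = c(backward = log(3) / 0.155,
                                     forward = log(3) / 0.18),
                         n1_latency_base_ms = 195,
                         n1_latency_accel_slope_ms = 6,
                         n1_latency_step_ms = -12,
                         n1_latency_jitter_ms = 4,
                         n1_amp_base = 8,
                         burst_amp_base = 6,
                         band_burst_gains = c(theta = 1, alpha = 0.6,
                                              beta = 0.4, gamma = 0),
                         amp_noise_sd = 1.5,
                         foot_off_base_ms = 650,
                         foot_off_accel_slope_ms = 120,
                         foot_off_sd_ms = 80,
                         mixing_matrix = default_mixing_matrix(),
                         source_noise_sd = c(midfrontal = 1, blink = 0.2,
                                             muscle = 1.5),
                         sensor_noise_sd = 0.2,
                         seed = 20201L) {
  accel_range <- range(default_accelerations())
  if (any(a50 < accel_range[1]) || any(a50 > accel_range[2]))
    stop("a50 must lie within the tested acceleration range [0.125, 2.5]")
  if (any(slope_k <= 0)) stop("slope_k must be positive")
  if (!all(c("backward", "forward") %in% names(a50)) ||
      !all(c("backward", "forward") %in% names(slope_k)))
    stop("a50 and slope_k must be named with 'backward' and 'forward'")
  if (qr(mixing_matrix)$rank < ncol(mixing_matrix))
    stop("mixing_matrix must have full column rank")
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         a50 = a50, slope_k = slope_k,
         n1_latency_base_ms = n1_latency_base_ms,
         n1_latency_accel_slope_ms = n1_latency_accel_slope_ms,
         n1_latency_step_ms = n1_latency_step_ms,
         n1_latency_jitter_ms = n1_latency_jitter_ms,
         n1_amp_base = n1_amp_base, burst_amp_base = burst_amp_base,
         band_burst_gains = band_burst_gains, amp_noise_sd = amp_noise_sd,
         foot_off_base_ms = foot_off_base_ms,
         foot_off_accel_slope_ms = foot_off_accel_slope_ms,
         foot_off_sd_ms = foot_off_sd_ms,
         mixing_matrix = mixing_matrix,
         source_noise_sd = source_noise_sd,
         sensor_noise_sd = sensor_noise_sd,
         seed = as.integer(seed)),
    class = "pep_ground_truth")
}

#' Generate a randomized trial schedule
#'
#' Builds blocks of 10 backward and 10 forward trials with intensities drawn
#' uniformly from the acceleration set (without replacement when the set has
#' at least 10 levels), order shuffled within each block.
#'
#' @param n_blocks Number of blocks (>= 1); 8 blocks of 20 trials give the
#'   typical 160-trial session.
#' @param accel_set Acceleration levels (m/s^2).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param participant_id Participant label attached to every trial.
#'
#' @return A trial table (data frame) with columns `participant_id`, `block`,
#'   `trial_id`, `direction`, `acceleration`, `stepped`, `foot_off_latency_ms`
#'   (the last two `NA` until [simulate_stepping()] fills them).
#' @export
generate_trial_schedule <- function(n_blocks, accel_set = default_accelerations(),
                                    seed = 1L, participant_id = "S01") {
  if (length(n_blocks) != 1 || is.na(n_blocks) || n_blocks < 1)
    stop("n_blocks must be a positive count")
  if (length(accel_set) == 0) stop("accel_set must be non-empty")
  set.seed(substream_seed(seed, "schedule"))
  blocks <- lapply(seq_len(n_blocks), function(b) {
    per_dir <- lapply(c("backward", "forward"), function(d) {
      acc <- if (length(accel_set) >= 10) sample(accel_set, 10)
             else sample(accel_set, 10, replace = TRUE)
      data.frame(direction = d, acceleration = acc, stringsAsFactors = FALSE)
    })
    blk <- do.call(rbind, per_dir)
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    blk$block <- b
    blk
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  data.frame(participant_id = participant_id, block = out$block,
             trial_id = seq_len(nrow(out)), direction = out$direction,
             acceleration = out$acceleration, stepped = NA,
             foot_off_latency_ms = NA_real_, stringsAsFactors = FALSE)
}

# inverse-CDF sampler for a truncated normal
rtruncated_normal <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate stepping outcomes and foot-off latencies
#'
#' Draws the stepping outcome of each trial from the logistic law
#' `p = 1 / (1 + exp(-k * (accel - a50)))` with direction-specific parameters,
#' and (for stepping trials) a foot-off latency from a truncated normal whose
#' mean decreases with acceleration, truncated to (150, 1000) ms so every step
#' falls inside the 1-s detection window.
#'
#' @param trials Trial table from [generate_trial_schedule()].
#' @param truth A [ground_truth()] object.
#' @param seed Optional override; defaults to the `behavior` substream of
#'   `truth$seed`.
#'
#' @return The trial table with `stepped` and `foot_off_latency_ms` filled;
#'   the ground truth used is attached as attribute `ground_truth`.
#' @export
simulate_stepping <- function(trials, truth, seed = NULL) {
  stopifnot(inherits(truth, "pep_ground_truth"))
  if (is.null(seed)) seed <- substream_seed(truth$seed, "behavior")
  set.seed(seed)
  p <- stepping_probability(trials$acceleration, trials$direction, truth)
  trials$stepped <- stats::runif(nrow(trials)) < p
  mu <- truth$foot_off_base_ms -
    truth$foot_off_accel_slope_ms * trials$acceleration
  lat <- rtruncated_normal(nrow(trials), mu, truth$foot_off_sd_ms, 150, 1000)
  trials$foot_off_latency_ms <- ifelse(trials$stepped, lat, NA_real_)
  attr(trials, "ground_truth") <- truth
  trials
}

#' Ground-truth stepping probability
#' @param accel Acceleration magnitudes (m/s^2).
#' @param direction `"backward"` or `"forward"` (recycled).
#' @param truth A [ground_truth()] object.
#' @return Probability of a stepping response per trial.
#' @export
stepping_probability <- function(accel, direction, truth) {
  k <- truth$slope_k[direction]
  a50 <- truth$a50[direction]
  stats::plogis(k * (accel - a50))
}

#' Generate two-plate vertical ground reaction forces for one trial
#'
#' During quiet stance the two traces sum to the bodyweight. On a stepping
#' trial the stepping foot unloads along a linear ramp that crosses 10 N
#' exactly at the configured foot-off latency and stays unloaded for at least
#' 400 ms; the stance foot takes up the complementary load. Non-stepping
#' trials sway the load slowly between feet, never dropping either trace below
#' a quarter of bodyweight.
#'
#' @param trial One row of a trial table (with `stepped` and
#'   `foot_off_latency_ms`).
#' @param fs Force-plate sampling rate (Hz).
#' @param bodyweight_N Bodyweight (N).
#' @param noise_sd Additive measurement noise SD (N); 0 gives exact traces.
#' @param seed Integer seed.
#' @param pre_s,post_s Seconds of trace before/after perturbation onset.
#'
#' @return List with elements `left`, `right` (force traces, N), `fs`,
#'   `onset_sample`, `stepping_foot` (`NA` if no step). Class `pep_grf`.
#' @export
generate_grf <- function(trial, fs = 2000, bodyweight_N = 700, noise_sd = 2,
                         seed = 1L, pre_s = 0.5, post_s = 2) {
  stopifnot(bodyweight_N > 0)
  set.seed(substream_seed(seed, paste0("grf", trial$trial_id[1])))
  n <- round((pre_s + post_s) * fs) + 1
  onset <- round(pre_s * fs) + 1
  t_rel <- (seq_len(n) - onset) / fs   # seconds relative to onset
  half <- bodyweight_N / 2

  if (isTRUE(trial$stepped)) {
    t_fo <- trial$foot_off_latency_ms / 1000
    t1 <- max(t_fo - 0.25, 0.05)                     # descent start
    # linear descent from half to 0 crossing 10 N exactly at t_fo
    t_zero <- t1 + (t_fo - t1) / (1 - 10 / half)
    stepping <- rep(half, n)
    desc <- t_rel >= t1
    stepping[desc] <- pmax(half * (1 - (t_rel[desc] - t1) / (t_zero - t1)), 0)
    # reload after a 400 ms swing phase
    t_reload <- t_zero + 0.4
    rel <- t_rel >= t_reload
    stepping[rel] <- pmin(half * (t_rel[rel] - t_reload) / 0.3, half)
    other <- bodyweight_N - stepping
    foot <- sample(c("left", "right"), 1)
    left <- if (foot == "left") stepping else other
    right <- if (foot == "left") other else stepping
  } else {
    sway <- 0.1 * bodyweight_N *
      sin(2 * pi * 0.8 * t_rel + stats::runif(1, 0, 2 * pi)) *
      pmin(pmax(t_rel / 0.3, 0), 1)   # sway builds up after onset
    left <- half + sway
    right <- half - sway
    foot <- NA_character_
  }
  if (noise_sd > 0) {
    left <- left + stats::rnorm(n, 0, noise_sd)
    right <- right + stats::rnorm(n, 0, noise_sd)
  }
  structure(list(left = left, right = right, fs = fs, onset_sample = onset,
                 stepping_foot = foot),
            class = "pep_grf")
}

# slow rectified envelope with unit mean (waxing/waning amplitude modulation)
slow_envelope <- function(n, fs, f_lo = 0.4) {
  e <- abs(as.numeric(signal::filtfilt(
    signal::butter(2, f_lo / (fs / 2), type = "low"), stats::rnorm(n))))
  e / mean(e)
}

# 1/f ("pink") background noise with unit SD, via spectral shaping
noise_one_over_f <- function(n, fs) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency axis
  scale <- 1 / sqrt(pmax(f, 1))      # flatten below 1 Hz
  x <- Re(stats::fft(spec * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# biphasic N1 template: small positive lobe then a unit-depth negative lobe,
# Gaussian-windowed; t_s is time relative to the trough
n1_template <- function(t_s) {
  0.3 * exp(-(t_s + 0.045)^2 / (2 * 0.020^2)) -
    exp(-t_s^2 / (2 * 0.028^2))
}

#' Generate a multichannel EEG recording with known injected structure
#'
#' The midfrontal source emits, per trial, an N1-shaped biphasic deflection at
#' latency `base - slope * accel` (shifted on stepping trials) whose trough
#' amplitude follows `10^(E/20)` with
#' `E = beta0 + beta1*ACCEL + beta2*STEP + beta3*ACCEL*STEP + noise` (dB), and
#' band-limited theta/alpha/beta bursts co-timed with the N1 whose log power
#' follows the same linear structure (band gains multiply the burst
#' amplitude). Background activity is 1/f noise; nuisance sources are blink
#' transients and broadband high-frequency muscle noise. Channel data are
#' `mixing_matrix %*% sources` plus white sensor noise.
#'
#' @param trials Trial table with stepping outcomes (see
#'   [simulate_stepping()]).
#' @param truth A [ground_truth()] object.
#' @param fs Sampling rate (Hz).
#' @param seed Optional override; defaults to the `eeg` substream of
#'   `truth$seed`.
#' @param iti_range_s Inter-trial onset interval range (s), drawn uniformly.
#' @param lead_in_s,tail_s Padding before the first / after the last onset (s).
#'
#' @return A [recording()] whose `events` hold one onset per trial, with
#'   attributes `ground_truth`, `injected` (per-trial data frame of injected
#'   dB values `E_n1`, `E_theta`, `E_alpha`, `E_beta` and `latency_ms`) and
#'   `sources` (the pre-mixing source matrix).
#' @export
generate_eeg <- function(trials, truth, fs = 512, seed = NULL,
                         iti_range_s = c(3, 5), lead_in_s = 5, tail_s = 4) {
  stopifnot(inherits(truth, "pep_ground_truth"))
  mix <- truth$mixing_matrix
  if (ncol(mix) != 3) stop("mixing_matrix must have 3 source columns")
  if (is.null(seed)) seed <- substream_seed(truth$seed, "eeg")
  set.seed(seed)
  n_tr <- nrow(trials)
  iti <- stats::runif(n_tr, iti_range_s[1], iti_range_s[2])
  onset_t <- lead_in_s + cumsum(c(0, iti[-1]))
  onsets <- round(onset_t * fs) + 1L
  n <- max(onsets) + round(tail_s * fs)

  src <- matrix(0, nrow = 3, ncol = n,
                dimnames = list(c("midfrontal", "blink", "muscle"), NULL))
  src["midfrontal", ] <- truth$source_noise_sd[["midfrontal"]] *
    noise_one_over_f(n, fs)

  bands <- band_definitions()
  X <- cbind(1, trials$acceleration, as.numeric(trials$stepped),
             trials$acceleration * as.numeric(trials$stepped))
  betas <- c(truth$beta0, truth$beta1, truth$beta2, truth$beta3)
  lin <- as.numeric(X %*% betas)

  E_n1 <- lin + stats::rnorm(n_tr, 0, truth$amp_noise_sd)
  lat_ms <- truth$n1_latency_base_ms -
    truth$n1_latency_accel_slope_ms * trials$acceleration +
    ifelse(trials$stepped, truth$n1_latency_step_ms, 0) +
    stats::rnorm(n_tr, 0, truth$n1_latency_jitter_ms)
  lat_ms <- pmin(pmax(lat_ms, 80), 290)

  E_band <- sapply(bands$band, function(b)
    lin + stats::rnorm(n_tr, 0, truth$amp_noise_sd))

  tmpl_idx <- round(seq(-0.15, 0.15, by = 1 / fs) * fs)
  for (i in seq_len(n_tr)) {
    center <- onsets[i] + round(lat_ms[i] / 1000 * fs)
    amp <- truth$n1_amp_base * 10^(E_n1[i] / 20)
    idx <- center + tmpl_idx
    ok <- idx >= 1 & idx <= n
    src["midfrontal", idx[ok]] <- src["midfrontal", idx[ok]] +
      amp * n1_template(tmpl_idx[ok] / fs)
    for (bi in seq_len(nrow(bands))) {
      g <- truth$band_burst_gains[[bands$band[bi]]]
      if (is.na(g) || g == 0) next
      sd_s <- bands$sd_s[bi]
      b_idx <- round(seq(-3 * sd_s, 3 * sd_s, by = 1 / fs) * fs)
      tt <- b_idx / fs
      burst_amp <- truth$burst_amp_base * g * 10^(E_band[i, bi] / 20)
      # bursts are phase-locked to the N1 (trough aligned), emulating the
      # phase-reset account of midfrontal rhythms; random phase would make
      # burst and N1 coefficients interfere destructively at low frequencies
      burst <- burst_amp * cos(2 * pi * bands$freq_hz[bi] * tt + pi) *
        exp(-tt^2 / (2 * sd_s^2))
      jdx <- center + b_idx
      ok <- jdx >= 1 & jdx <= n
      src["midfrontal", jdx[ok]] <- src["midfrontal", jdx[ok]] + burst[ok]
    }
  }

  # blink transients (positive slow lobes) + low background
  n_blinks <- stats::rpois(1, 0.12 * n / fs)
  if (n_blinks > 0) {
    b_centers <- sort(sample.int(n, n_blinks))
    b_idx <- round(seq(-0.2, 0.2, by = 1 / fs) * fs)
    for (c0 in b_centers) {
      idx <- c0 + b_idx
      ok <- idx >= 1 & idx <= n
      src["blink", idx[ok]] <- src["blink", idx[ok]] +
        40 * exp(-(b_idx[ok] / fs)^2 / (2 * 0.06^2))
    }
  }
  src["blink", ] <- src["blink", ] +
    stats::rnorm(n, 0, truth$source_noise_sd[["blink"]])

  # broadband muscle: white noise high-passed at 30 Hz, amplitude-modulated by
  # a slow rectified envelope (EMG-like activity bursts)
  hp <- signal::butter(4, 30 / (fs / 2), type = "high")
  src["muscle", ] <- truth$source_noise_sd[["muscle"]] *
    as.numeric(signal::filtfilt(hp, stats::rnorm(n))) * slow_envelope(n, fs)

  # per-channel sensor/electrode noise, amplitude-modulated by an independent
  # slow envelope per channel (electrode noise is bursty, not stationary)
  dat <- mix %*% src
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- dat[ch, ] + truth$sensor_noise_sd *
      stats::rnorm(n) * slow_envelope(n, fs)
  roles <- attr(mix, "channel_roles")
  if (is.null(roles)) roles <- rep("scalp", nrow(mix))

  rec <- recording(dat, fs, channel_roles = roles,
                   events = data.frame(sample = onsets,
                                       trial_id = trials$trial_id))
  attr(rec, "ground_truth") <- truth
  attr(rec, "injected") <- data.frame(
    trial_id = trials$trial_id, acceleration = trials$acceleration,
    stepped = trials$stepped, E_n1 = E_n1,
    E_theta = E_band[, "theta"], E_alpha = E_band[, "alpha"],
    E_beta = E_band[, "beta"], latency_ms = lat_ms,
    onset_sample = onsets, stringsAsFactors = FALSE)
  attr(rec, "sources") <- src
  rec
}
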