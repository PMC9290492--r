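# Generator: trial schedules, stepping law, ground reaction forces and EEG
# with known injected structure.

test_that("trial schedules have the block structure of a session", {
  sched <- generate_trial_schedule(8, seed = 1)
  expect_equal(nrow(sched), 160)
  expect_equal(as.numeric(table(sched$direction)), c(80, 80))

  one <- generate_trial_schedule(1, seed = 2)
  expect_equal(sum(one$direction == "backward"), 10)
  expect_equal(sum(one$direction == "forward"), 10)
  # >= 10 levels: within-block draw is without replacement
  for (d in c("backward", "forward"))
    expect_equal(anyDuplicated(one$acceleration[one$direction == d]), 0)
  expect_true(all(one$acceleration %in% default_accelerations()))

  expect_identical(generate_trial_schedule(3, seed = 9),
                   generate_trial_schedule(3, seed = 9))
  expect_error(generate_trial_schedule(0), "positive")
})

test_that("stepping simulation follows the logistic law", {
  truth <- ground_truth()
  expect_equal(stepping_probability(truth$a50[["backward"]], "backward", truth),
               0.5, ignore_attr = TRUE)
  expect_equal(stepping_probability(truth$a50[["forward"]], "forward", truth),
               0.5, ignore_attr = TRUE)

  # step-function limit
  hard <- ground_truth(slope_k = c(backward = 1e3, forward = 1e3))
  sched <- generate_trial_schedule(10, seed = 3)
  sim <- simulate_stepping(sched, hard, seed = 4)
  above <- sim$acceleration > hard$a50[sim$direction] + 0.01
  below <- sim$acceleration < hard$a50[sim$direction] - 0.01
  expect_true(all(sim$stepped[above]))
  expect_false(any(sim$stepped[below]))

  # latencies present iff stepped, inside the detection window
  sim2 <- make_session()
  expect_true(all(is.na(sim2$foot_off_latency_ms) == !sim2$stepped))
  lat <- sim2$foot_off_latency_ms[sim2$stepped]
  expect_true(all(lat > 150 & lat < 1000))
  expect_s3_class(attr(sim2, "ground_truth"), "pep_ground_truth")
})

test_that("logistic refit recovers the configured 50% points", {
  truth <- ground_truth()
  trials <- do.call(rbind, lapply(1:10, function(i)
    generate_trial_schedule(7, seed = 200 + i,
                            participant_id = sprintf("S%02d", i))))
  trials <- simulate_stepping(trials, truth, seed = 42)
  expect_gte(nrow(trials), 1400)
  for (d in c("backward", "forward")) {
    m <- fit_step_probability(trials, d)
    expect_false(m$separation)
    expect_lt(abs(m$a50 - truth$a50[[d]]), 0.1)
  }
})

test_that("ground truth validates its invariants", {
  expect_error(ground_truth(a50 = c(backward = 3, forward = 1.28)), "range")
  expect_error(ground_truth(slope_k = c(backward = -1, forward = 6)),
               "positive")
  bad_mix <- default_mixing_matrix()
  bad_mix[, 2] <- bad_mix[, 1]
  expect_error(ground_truth(mixing_matrix = bad_mix), "rank")
})

test_that("ground reaction forces support exact round trips", {
  sim <- make_session()
  ns_trial <- sim[which(!sim$stepped)[1], ]
  g0 <- generate_grf(ns_trial, noise_sd = 0, seed = 7)
  expect_equal(max(abs(g0$left + g0$right - 700)), 0)   # quiet stance sums to BW
  expect_gt(min(g0$left, g0$right), 10)

  gn <- generate_grf(ns_trial, seed = 8)
  ev <- detect_step(gn$left, gn$right, gn$fs, gn$onset_sample)
  expect_false(ev$stepped)

  st_trial <- sim[which(sim$stepped)[1], ]
  st_trial$foot_off_latency_ms <- 600
  g1 <- generate_grf(st_trial, seed = 9)
  ev1 <- detect_step(g1$left, g1$right, g1$fs, g1$onset_sample)
  expect_true(ev1$stepped)
  expect_lt(abs(ev1$foot_off_latency_ms - 600), 10)
})

test_that("EEG generation is deterministic and carries its ground truth", {
  truth <- ground_truth(seed = 55)
  sim <- make_session(1, 55, truth)
  r1 <- generate_eeg(sim, truth)
  r2 <- generate_eeg(sim, truth)
  expect_identical(r1$samples, r2$samples)
  expect_identical(attr(r1, "injected"), attr(r2, "injected"))
  expect_s3_class(attr(r1, "ground_truth"), "pep_ground_truth")
  expect_equal(nrow(r1$events), nrow(sim))
  expect_true(all(diff(r1$events$sample) > 0))
})

test_that("null effects give identical N1 deflections across accelerations", {
  truth <- ground_truth(beta1 = 0, beta2 = 0, beta3 = 0, amp_noise_sd = 0,
                        n1_latency_jitter_ms = 0,
                        band_burst_gains = c(theta = 0, alpha = 0, beta = 0,
                                             gamma = 0),
                        source_noise_sd = c(midfrontal = 0, blink = 0,
                                            muscle = 0),
                        sensor_noise_sd = 0, seed = 66)
  sim <- make_session(1, 66, truth)
  rec <- generate_eeg(sim, truth)
  src <- attr(rec, "sources")["midfrontal", ]
  inj <- attr(rec, "injected")
  troughs <- vapply(seq_len(nrow(inj)), function(i) {
    onset <- inj$onset_sample[i]
    min(src[onset:(onset + round(0.3 * rec$fs))])
  }, numeric(1))
  expect_lt(diff(range(troughs)) / abs(mean(troughs)), 1e-6)
})

test_that("source-level regression recovers the injected effect sizes", {
  # noiseless: exact recovery to solver tolerance
  exact <- ground_truth(amp_noise_sd = 0, seed = 77)
  sim <- make_session(2, 77, exact)
  inj <- attr(generate_eeg(sim, exact), "injected")
  fit <- fit_glm(inj$E_n1, data.frame(accel = inj$acceleration,
                                      step = as.numeric(inj$stepped)))
  expect_equal(fit$coefficients$estimate,
               c(exact$beta0, exact$beta1, exact$beta2, exact$beta3),
               tolerance = 1e-8)

  # noisy, 300+ trials: each coefficient within 3 SEs
  truth <- ground_truth(seed = 88)
  sim2 <- make_session(8, 88, truth)
  inj2 <- attr(generate_eeg(sim2, truth), "injected")
  fit2 <- fit_glm(inj2$E_n1, data.frame(accel = inj2$acceleration,
                                        step = as.numeric(inj2$stepped)))
  z <- (fit2$coefficients$estimate -
          c(truth$beta0, truth$beta1, truth$beta2, truth$beta3)) /
    fit2$coefficients$se
  expect_true(all(abs(z) < 3))
})
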