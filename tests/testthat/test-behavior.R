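# Step detection and the behavioural statistics battery.

make_trace <- function(n, value = 700) rep(value, n)

test_that("detect_step classifies crossings against the filtered trace", {
  fs <- 2000
  n <- 3 * fs
  onset <- fs
  flat <- make_trace(n)
  ev <- detect_step(flat, flat, fs, onset)
  expect_false(ev$stepped)

  # descending ramp crossing 10 N at 600 ms; oracle = brute-force first
  # crossing on the independently filtered trace
  t_rel <- (seq_len(n) - onset) / fs
  ramp <- pmax(350 * (1 - (t_rel - 0.35) / (0.2555 / (1 - 10 / 350))), 0)
  ramp[t_rel < 0.35] <- 350
  bf <- signal::butter(5, 20 / (fs / 2), type = "low")
  filtered <- as.numeric(signal::filtfilt(bf, ramp))
  oracle_hit <- which(filtered[(onset + 1):(onset + fs)] < 10)[1]
  ev2 <- detect_step(ramp, flat, fs, onset)
  expect_true(ev2$stepped)
  expect_equal(ev2$foot_off_latency_ms, floor(oracle_hit / fs * 1000))
  expect_identical(ev2$foot, "left")

  # crossing only at 1200 ms is outside the 1-s window
  late <- make_trace(n)
  late[t_rel > 1.2] <- 0
  ev3 <- detect_step(late, flat, fs, onset)
  expect_false(ev3$stepped)

  expect_error(detect_step(flat[1:(onset + 100)], flat[1:(onset + 100)],
                           fs, onset), "window")
})

test_that("detection is offset-invariant above threshold and monotone in threshold", {
  fs <- 500
  n <- 2 * fs
  onset <- round(0.5 * fs)
  set.seed(31)
  for (i in 1:5) {
    base <- 300 + 50 * sin(2 * pi * 0.7 * seq_len(n) / fs + runif(1, 0, 6))
    drop_at <- onset + round(fs * runif(1, 0.2, 0.8))
    trace <- base
    trace[drop_at:n] <- pmax(base[drop_at:n] - (seq_len(n - drop_at + 1)) * 3, 0)
    other <- make_trace(n, 400)
    ev10 <- detect_step(trace, other, fs, onset)
    ev_off <- detect_step(trace + 100, other + 100, fs, onset)
    expect_false(ev_off$stepped && !ev10$stepped)
    ev5 <- detect_step(trace, other, fs, onset, threshold_N = 5)
    if (ev5$stepped && ev10$stepped)
      expect_gte(ev5$foot_off_latency_ms, ev10$foot_off_latency_ms)
    expect_false(ev5$stepped && !ev10$stepped)
  }
})

test_that("stepping-probability fit matches a known logistic and flags separation", {
  set.seed(11)
  n <- 500
  accel <- sample(default_accelerations(), n, replace = TRUE)
  p <- plogis(8 * (accel - 1.0))
  trials <- data.frame(direction = "backward", acceleration = accel,
                       stepped = runif(n) < p)
  m <- fit_step_probability(trials, "backward")
  expect_false(m$separation)
  expect_gt(m$a50, 0.9)
  expect_lt(m$a50, 1.1)
  expect_lt(m$a25, m$a50)
  expect_lt(m$a50, m$a75)
  expect_equal(predict_step_probability(m, m$a50), 0.5, tolerance = 1e-8)

  all_step <- data.frame(direction = "backward",
                         acceleration = accel[1:50], stepped = TRUE)
  expect_warning(ms <- fit_step_probability(all_step, "backward"),
                 "separation")
  expect_true(ms$separation)
})

test_that("chi-square matches hand and brute-force expected-count computations", {
  res <- contingency_chi_square(20, 10, 10, 20)
  expect_equal(res$chi2, 100 / 15, tolerance = 1e-10)
  expect_equal(res$df, 1)

  expect_equal(contingency_chi_square(50, 50, 50, 50)$chi2, 0)

  set.seed(5)
  for (i in 1:10) {
    cts <- rpois(4, 30) + 1
    tab <- matrix(cts, 2, byrow = TRUE)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - expd)^2 / expd)
    expect_equal(contingency_chi_square(cts[1], cts[2], cts[3], cts[4])$chi2,
                 oracle, tolerance = 1e-10)
  }
  expect_error(contingency_chi_square(0, 0, 5, 5), "marginal")
})

test_that("paired t test matches closed forms and handles degeneracy", {
  r <- paired_t_test(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)  # diffs (1,2,3)
  expect_equal(r$df, 2)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_true(same$degenerate)

  shift <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_identical(shift$t, Inf)
  expect_true(shift$degenerate)

  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("pooled weighted mean weights participant means by trial counts", {
  expect_equal(pooled_weighted_mean(c(100, 200), c(1, 3)), 175)
  expect_equal(pooled_weighted_mean(c(2, 4, 6), c(5, 5, 5)), 4)
  expect_error(pooled_weighted_mean(c(1, 2), c(1, 2, 3)), "mismatch")
  expect_error(pooled_weighted_mean(c(1, 2), c(1, 0)), "positive")
})

test_that("KS uniformity statistic matches a direct ECDF comparison", {
  r <- ks_uniformity(1.3125, 0.125, 2.5)   # single midpoint value
  expect_equal(r$D, 0.5, tolerance = 1e-10)

  grid <- rep(default_accelerations(), times = 4)
  # oracle: max deviation between the step ECDF and the uniform CDF
  u <- sort(unique(grid))
  cdf <- punif(u, 0.125, 2.5)
  ecdf_hi <- seq_along(u) / length(u)
  ecdf_lo <- (seq_along(u) - 1) / length(u)
  oracle_D <- max(pmax(abs(ecdf_hi - cdf), abs(ecdf_lo - cdf)))
  r2 <- ks_uniformity(grid, 0.125, 2.5)
  expect_equal(r2$D, oracle_D, tolerance = 1e-10)

  expect_error(ks_uniformity(c(0.5, 3), 0.125, 2.5), "range")

  set.seed(8)
  smoke <- ks_uniformity(runif(695, 0.125, 2.5), 0.125, 2.5)
  expect_true(smoke$p >= 0 && smoke$p <= 1)
})

test_that("behavioural report reproduces table-derived invariants", {
  tabs <- load_summary_tables()
  rep <- behavioral_report(tabs$table1, tabs$table2)
  # pooled counts equal the sum of per-participant counts
  expect_equal(rep$counts$step_b, sum(tabs$table1$steps_backward))
  expect_equal(rep$n_backward, 695)
  expect_equal(rep$n_forward, 676)
  # recomputed backward proportion is 63.6% (442/695)
  expect_equal(rep$prop_step_backward, 100 * 442 / 695, tolerance = 1e-10)
  # pooled weighted N1 mean, stepping backward
  expect_equal(unname(rep$pooled_n1_ms["step_backward"]), 174.5,
               tolerance = 0.05)

  # identical latencies give zero paired t statistics
  t2 <- tabs$table2
  t2$n1_nonstep_backward_ms <- t2$n1_step_backward_ms
  t2$n1_nonstep_forward_ms <- t2$n1_step_forward_ms
  rep2 <- behavioral_report(tabs$table1, t2)
  expect_equal(rep2$t_n1_backward$t, 0)
  expect_equal(rep2$t_n1_forward$t, 0)
})

test_that("summarize_trials aggregates trial-level data into the table shape", {
  sim <- rbind(
    make_session(2, 300),
    simulate_stepping(generate_trial_schedule(2, seed = 301,
                                              participant_id = "S02"),
                      ground_truth(seed = 301)))
  n1 <- 190 - 10 * as.numeric(sim$stepped) + rnorm(nrow(sim), 0, 2)
  tabs <- summarize_trials(sim, n1)
  expect_equal(nrow(tabs$table1), 2)
  expect_equal(sum(tabs$table1$steps_backward + tabs$table1$nonsteps_backward),
               sum(sim$direction == "backward"))
  rep <- behavioral_report(tabs$table1, tabs$table2)
  expect_lt(rep$t_n1_backward$t, 0)   # stepping N1 earlier by construction
})
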