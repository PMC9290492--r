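# Pooled single-trial regression machinery and FDR control.

make_design <- function(n, seed = 1) {
  set.seed(seed)
  accel <- sample(default_accelerations(), n, replace = TRUE)
  step <- as.numeric(runif(n) < plogis(7 * (accel - 1.1)))
  # guarantee full rank
  step[1:4] <- c(0, 0, 1, 1)
  accel[1:4] <- c(0.5, 1.0, 1.5, 2.0)
  data.frame(accel = accel, step = step)
}

test_that("participant z-scoring normalises within participant", {
  set.seed(71)
  ids <- rep(c("S01", "S02"), each = 50)
  v <- c(rnorm(50, 100, 20), rnorm(50, -3, 0.1))
  z <- zscore_by_participant(v, ids)
  for (id in unique(ids)) {
    expect_lt(abs(mean(z[ids == id])), 1e-10)
    expect_equal(sd(z[ids == id]), 1, tolerance = 1e-10)
  }
  # affine invariance within a participant
  v2 <- v
  v2[ids == "S01"] <- 3 * v[ids == "S01"] + 17
  expect_equal(zscore_by_participant(v2, ids), z, tolerance = 1e-10)

  expect_error(zscore_by_participant(c(1, 1, 2, 3), c("A", "A", "B", "B")),
               "A")
})

test_that("single-bin fit matches lm and recovers simulated coefficients", {
  design <- make_design(600, seed = 72)
  set.seed(73)
  C <- 0.5 * design$accel + 0.3 * design$step -
    0.4 * design$accel * design$step + rnorm(600)
  fit <- fit_glm(C, design)

  # oracle: base R lm on the same model
  ref <- lm(C ~ accel * step, data = design)
  s <- summary(ref)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(s$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(fit$coefficients$p, unname(s$coefficients[, 4]),
               tolerance = 1e-10)
  expect_equal(fit$adj_r2, s$adj.r.squared, tolerance = 1e-10)
  expect_equal(fit$f, unname(s$fstatistic[1]), tolerance = 1e-10)
  expect_equal(fit$coefficients[, c("ci_lo", "ci_hi")],
               as.data.frame(unname(confint(ref))),
               ignore_attr = TRUE, tolerance = 1e-10)

  z <- (fit$coefficients$estimate - c(0, 0.5, 0.3, -0.4)) / fit$coefficients$se
  expect_true(all(abs(z) < 3))

  # constant response: no crash, undefined R^2 reported as NA
  fit0 <- fit_glm(rep(1, 600), design)
  expect_equal(fit0$coefficients$estimate[-1], rep(0, 3), tolerance = 1e-10)
  expect_true(is.na(fit0$r2))

  # rank deficiency identifies the offending column
  bad <- design; bad$step <- 1
  expect_error(fit_glm(C, bad), "step")
  bad2 <- design; bad2$accel[bad2$step == 1] <- 2
  expect_error(fit_glm(C, bad2), "accel")
})

test_that("F-test p-values are uniform under the null", {
  design <- make_design(120, seed = 74)
  set.seed(75)
  pvals <- replicate(200, fit_glm(rnorm(120), design)$p_f)
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mass-univariate grid matches per-bin lm fits", {
  design <- make_design(80, seed = 76)
  set.seed(77)
  Y <- matrix(rnorm(80 * 12), 80, 12)
  Y[, 3] <- Y[, 3] + design$accel            # one real effect
  grid <- mass_univariate(Y, design, alpha = 0.05, method = "BY")
  for (j in c(1, 3, 7)) {
    ref <- fit_glm(Y[, j], design)
    expect_equal(grid$beta[, j], ref$coefficients$estimate,
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(grid$se[, j], ref$coefficients$se, ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(grid$p[, j], ref$coefficients$p, ignore_attr = TRUE,
                 tolerance = 1e-8)
    expect_equal(grid$adj_r2[j], ref$adj_r2, tolerance = 1e-8)
    expect_equal(grid$f[j], ref$f, tolerance = 1e-8)
  }
  # FDR per coefficient family across bins
  expect_equal(grid$p_adj["accel", ],
               p.adjust(grid$p["accel", ], method = "BY"))
  # degenerate bin collected, not fatal
  Y2 <- Y; Y2[, 5] <- 2
  g2 <- mass_univariate(Y2, design)
  expect_equal(g2$failed_bins, 5L, ignore_attr = TRUE)
  expect_true(is.na(g2$adj_r2[5]))
})

test_that("BY correction matches the hand-computed example and bounds BH", {
  fc <- fdr_correct(c(0.001, 0.02, 0.9), alpha = 0.01)
  cm <- 1 + 1 / 2 + 1 / 3
  expect_equal(fc$p_adj, c(0.001 * 3 * cm / 1, 0.02 * 3 * cm / 2, 1),
               tolerance = 1e-12)
  expect_equal(fc$mask, c(TRUE, FALSE, FALSE))

  expect_equal(fdr_correct(rep(1, 5))$mask, rep(FALSE, 5))
  # a single test reduces to the raw comparison
  expect_equal(fdr_correct(0.005, alpha = 0.01)$p_adj, 0.005)
  expect_true(fdr_correct(0.005, alpha = 0.01)$mask)
  expect_length(fdr_correct(numeric(0))$p_adj, 0)

  set.seed(78)
  for (i in 1:10) {
    p <- runif(50)^2
    by <- fdr_correct(p, alpha = 0.05, method = "BY")$mask
    bh <- fdr_correct(p, alpha = 0.05, method = "BH")$mask
    expect_true(all(!by | bh))   # BY never rejects what BH keeps
  }
})

test_that("label permutation destroys significance of real effects", {
  design <- make_design(600, seed = 82)
  set.seed(83)
  Y <- matrix(rnorm(600 * 40), 600, 40)
  X_eff <- with(design, 2 * accel + 1.5 * step - 1.5 * accel * step)
  Y <- Y + X_eff            # every bin carries the injected structure
  g1 <- mass_univariate(Y, design)
  expect_gt(mean(g1$mask["accel", ]), 0.9)
  expect_gt(mean(g1$mask["accel_step", ]), 0.5)
  perm <- sample(nrow(Y))
  g0 <- mass_univariate(Y[perm, ], design)
  expect_lte(mean(g0$mask[c("accel", "step", "accel_step"), ]), 0.01)
})

test_that("stepping attenuates the fitted intensity slope (interaction)", {
  truth <- ground_truth(seed = 79)
  sim <- make_session(10, 79, truth)
  inj <- attr(generate_eeg(sim, truth), "injected")
  fit <- fit_glm(inj$E_n1, data.frame(accel = inj$acceleration,
                                      step = as.numeric(inj$stepped)))
  b <- fit$coefficients$estimate
  slope_nonstep <- b[2]
  slope_step <- b[2] + b[4]
  expect_gt(slope_nonstep, slope_step)
  expect_gt(slope_nonstep, 0)
  expect_lt(b[4], 0)
})

test_that("latency regression finds the injected latency law and not noise", {
  design <- make_design(600, seed = 80)
  set.seed(81)
  lat <- 195 - 6 * design$accel - 12 * design$step + rnorm(600, 0, 4)
  z <- (lat - mean(lat)) / sd(lat)
  fit <- n1_latency_regression(z, design)
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "accel"], 0)
  expect_lt(co$estimate[co$term == "step"], 0)
  expect_lt(co$p[co$term == "accel"], 0.01)
  expect_lt(co$p[co$term == "step"], 0.01)

  null_fit <- n1_latency_regression(rnorm(600), design)
  expect_gt(min(null_fit$coefficients$p), 1e-4)   # no spurious certainty
})
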