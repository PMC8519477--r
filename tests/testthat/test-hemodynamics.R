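## Clinical indices: quadrature oracles on constructed beats, summary
## consistency on simulated beats, reference-range validation.

test_that("cardiac output integrates the outflow trace", {
  T <- 60 / 105
  t <- seq(0, T, length.out = 2000)
  ## constant flow: mean of a constant
  expect_equal(cardiac_output(synthetic_beat(t, rep(40, length(t)), T)),
               2.4)
  ## half-sine ejection: closed-form integral (2/pi) * peak * duration / T
  dur <- 0.2; peak <- 200
  Q <- ifelse(t <= dur, peak * sin(pi * t / dur), 0)
  co_expected <- (2 / pi) * peak * dur / T * 60 / 1000
  expect_equal(co_expected, 2.67, tolerance = 1e-2)
  expect_equal(cardiac_output(synthetic_beat(t, Q, T)), co_expected,
               tolerance = 1e-5)
  ## linearity: scaling the trace scales CO
  expect_equal(cardiac_output(synthetic_beat(t, 3 * Q, T)),
               3 * cardiac_output(synthetic_beat(t, Q, T)))
})

test_that("ejection window recovers constructed bounds", {
  T <- 60 / 105
  t <- seq(0, T, length.out = 2000)
  dt <- t[2] - t[1]
  Q <- ifelse(t >= 0.1 & t <= 0.3, 100, 0)
  ew <- ejection_window(synthetic_beat(t, Q, T))
  expect_lt(abs(ew$t_start - 0.1), dt + 1e-12)
  expect_lt(abs(ew$t_end - 0.3), dt + 1e-12)
  expect_lt(abs(ew$T_e - 0.2), 3 * dt)
})

test_that("degenerate ejection patterns are reported", {
  T <- 60 / 105
  t <- seq(0, T, length.out = 500)
  expect_error(ejection_window(synthetic_beat(t, rep(0, length(t)), T)),
               "no ejection")
  ## a valve that never closes (severe-obstruction trickle regime): the
  ## single contiguous window is the whole period
  ew <- ejection_window(synthetic_beat(t, rep(10, length(t)), T))
  expect_equal(ew$T_e, T)
  Q2 <- ifelse((t > 0.05 & t < 0.15) | (t > 0.3 & t < 0.4), 50, 0)
  expect_error(ejection_window(synthetic_beat(t, Q2, T)),
               "multiple distinct ejection windows")
})

test_that("a wrapped ejection window is handled on the periodic extension", {
  T <- 60 / 105
  t <- seq(0, T, length.out = 2000)
  Q <- ifelse(t < 0.1 | t > T - 0.05, 80, 0)
  ew <- ejection_window(synthetic_beat(t, Q, T))
  expect_equal(ew$T_e, 0.15, tolerance = 0.01)
  expect_gt(ew$t_end, T)
})

test_that("mean gradient over ejection reproduces a constant plateau", {
  T <- 60 / 105
  t <- seq(0, T, length.out = 2000)
  Q <- ifelse(t >= 0.1 & t <= 0.3, 120, 0)
  b <- synthetic_beat(t, Q, T, narrowing_ratio = 0.4)
  K <- compute_K_obs(b$geom)
  ## a rectangular plateau's true edges are ambiguous by half a sample
  expect_equal(mean_obstruction_gradient(b), K * 120^2, tolerance = 2e-3)
  ## no obstruction: identically zero
  b0 <- synthetic_beat(t, Q, T, side = "NONE", narrowing_ratio = 1)
  expect_identical(mean_obstruction_gradient(b0), 0)
  ## but the Doppler gradient through the open conduit stays finite
  expect_gt(doppler_summary(b0)[["mean"]], 0)
})

test_that("peak gradient dominates the mean and tracks peak flow", {
  b <- obstructed_beat(0.3)
  expect_gte(peak_obstruction_gradient(b), mean_obstruction_gradient(b))
  expect_equal(peak_obstruction_gradient(b),
               compute_K_obs(b$geom) * max(b$Q_vot)^2)
  dop <- doppler_summary(b)
  expect_gte(dop[["peak"]], dop[["mean"]])
  ## pressure-recovery property, pointwise in time
  expect_true(all(b$dp_doppler >= b$dp_obs))
})

test_that("summary fields are internally consistent on the baseline", {
  s <- summarize_beat(baseline_beat())
  expect_gte(s$SBP, s$MAP); expect_gte(s$MAP, s$DBP)
  expect_gt(s$T_e, 0); expect_lt(s$T_e, baseline_beat()$T)
  expect_equal(s$SVR, (s$MAP - s$p_RA_mean) / (s$CO * 1000 / 60))
  expect_gte(s$dp_doppler_mean, s$dp_obs_mean)
  expect_identical(s$dp_obs_mean, 0)
  ## semilunar valves are normo-functioning: mean systolic drop 1-2 mmHg
  expect_lte(s$dp_valve_mean, 2)
})

test_that("quadrature is converged at the default sampling", {
  ## halve the sampling of the same converged trace: the quadrature error at
  ## the default density must be below 1e-4 relative
  b <- baseline_beat()
  idx <- seq(1L, length(b$t), by = 2L)
  co_full <- cardiac_output(b)
  co_half <- cardiac_output(synthetic_beat(b$t[idx], b$Q_vot[idx], b$T))
  expect_lt(abs(co_half - co_full) / co_full, 1e-4)
  dp_full <- mean_obstruction_gradient(obstructed_beat(0.3))
  ob <- obstructed_beat(0.3)
  dp_half <- mean_obstruction_gradient(
    synthetic_beat(ob$t[idx], ob$Q_vot[idx], ob$T, narrowing_ratio = 0.3))
  expect_lt(abs(dp_half - dp_full) / dp_full, 1e-3)
})

test_that("obstruction lengthens and flattens the ejection waveform", {
  base <- summarize_beat(baseline_beat())
  obs <- summarize_beat(obstructed_beat(0.3))
  expect_gt(obs$T_e, base$T_e)
  expect_lt(obs$Q_peak, base$Q_peak)
  ## delayed peak
  tpk_base <- baseline_beat()$t[which.max(baseline_beat()$Q_vot)]
  tpk_obs <- obstructed_beat(0.3)$t[which.max(obstructed_beat(0.3)$Q_vot)]
  expect_gt(tpk_obs, tpk_base)
})

test_that("reference-range validation reports without raising", {
  rng <- reference_ranges()
  expect_true(all(rng$low <= rng$high))
  ## midpoints all pass
  mid <- as.data.frame(as.list(setNames((rng$low + rng$high) / 2,
                                        rng$quantity)))
  rep_mid <- validate_against_reference(mid, rng)
  expect_true(all(rep_mid$pass))
  ## circulatory collapse fails the CO range
  mid$CO <- 0
  rep0 <- validate_against_reference(mid, rng)
  expect_false(rep0$pass[rep0$quantity == "CO"])
  ## the calibrated baseline hits the principal ranges
  rep_base <- validate_against_reference(summarize_beat(baseline_beat()), rng)
  key <- c("SVR", "SBP", "p_LV_sys", "p_RV_sys", "p_PuA_sys",
           "p_LA_mean", "p_RA_mean", "CO")
  expect_true(all(rep_base$pass[rep_base$quantity %in% key]))
})
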