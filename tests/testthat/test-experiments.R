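## Severity sweeps, threshold crossings, shape-factor and parameter
## sensitivity.  Coarse ratio grids keep single tests fast; the full default
## grid is exercised by the acceptance suite.

coarse <- seq(1, 0.2, by = -0.1)

lvot_coarse <- function() memo("lvot_coarse",
  narrowing_sweep(baseline_params(), "LVOT", ratios = coarse))
rvot_coarse <- function() memo("rvot_coarse",
  narrowing_sweep(baseline_params(), "RVOT", ratios = coarse))

test_that("the unobstructed sweep row equals the baseline run", {
  sw <- lvot_coarse()
  expect_equal(sw$narrowing_ratio[1L], 1)      # sorted descending
  base <- summarize_beat(baseline_beat())
  row1 <- sw[1L, ]
  for (q in c("CO", "SBP", "DBP", "MAP", "dp_obs_mean", "Q_peak", "T_e"))
    expect_equal(row1[[q]], base[[q]], tolerance = 1e-6)
})

test_that("gradient falls and CO rises with the narrowing ratio", {
  for (sw in list(lvot_coarse(), rvot_coarse())) {
    expect_true(all(diff(sw$narrowing_ratio) < 0))
    ## along descending ratio: gradient non-decreasing, CO non-increasing
    ## (CO slack at the periodic-steady-state residual, 1e-3 relative)
    expect_true(all(diff(sw$dp_obs_mean) >= -1e-9))
    expect_true(all(diff(sw$CO) <= 1e-3 * max(sw$CO)))
    expect_true(all(diff(sw$dp_doppler_mean) >= -1e-9))
  }
})

test_that("left obstructions raise larger gradients than right ones", {
  l <- lvot_coarse(); r <- rvot_coarse()
  shared <- intersect(l$narrowing_ratio, r$narrowing_ratio)
  shared <- shared[shared < 1]
  dl <- l$dp_obs_mean[match(shared, l$narrowing_ratio)]
  dr <- r$dp_obs_mean[match(shared, r$narrowing_ratio)]
  expect_true(all(dl > dr))
})

test_that("right obstructions depress CO more at matched moderate ratios", {
  l <- lvot_coarse(); r <- rvot_coarse()
  shared <- intersect(l$narrowing_ratio, r$narrowing_ratio)
  shared <- shared[shared < 0.45]     # moderate-to-severe range
  expect_gte(length(shared), 2L)
  co_l <- l$CO[match(shared, l$narrowing_ratio)]
  co_r <- r$CO[match(shared, r$narrowing_ratio)]
  expect_true(all(co_r < co_l))
})

test_that("threshold crossing interpolates monotone sweeps", {
  ## synthetic monotone table with a known inverse
  tab <- data.frame(narrowing_ratio = seq(0.2, 1, by = 0.1))
  tab$dp <- 50 * (1 - tab$narrowing_ratio)^2
  ## exact grid value returns the grid ratio
  expect_identical(threshold_crossing(tab, "dp", 50 * 0.36), 0.4)
  ## interior values agree with a brute-force fine inversion
  fine <- data.frame(narrowing_ratio = seq(0.2, 1, by = 0.001))
  fine$dp <- 50 * (1 - fine$narrowing_ratio)^2
  for (thr in c(3, 11, 24)) {
    coarse_hit <- threshold_crossing(tab, "dp", thr)
    fine_hit <- threshold_crossing(fine, "dp", thr)
    expect_lt(abs(coarse_hit - fine_hit), 0.1)   # one coarse grid step
  }
  ## out-of-range thresholds are an explicit no-crossing result
  miss <- threshold_crossing(tab, "dp", 1000)
  expect_true(is.na(miss))
  expect_match(attr(miss, "message"), "outside swept range")
})

test_that("shape factor inflates gradients and shifts crossings", {
  ratios <- c(0.6, 0.5, 0.45, 0.4, 0.35)
  fs <- fshape_sensitivity(baseline_params(), "LVOT",
                           fshape_values = c(1, 2), ratios = ratios)
  s1 <- fs[fs$f_shape == 1, ]
  s2 <- fs[fs$f_shape == 2, ]
  ## f_shape = 1 slice identical to the plain sweep
  plain <- narrowing_sweep(baseline_params(), "LVOT", ratios = ratios)
  expect_equal(s1$dp_obs_mean, plain$dp_obs_mean, tolerance = 1e-9)
  ## pointwise gradient dominance at matched ratios
  expect_true(all(s2$dp_obs_mean > s1$dp_obs_mean))
  ## a fixed-gradient crossing moves to larger (milder) ratios
  thr <- 20
  expect_gt(threshold_crossing(s2, "dp_obs_mean", thr),
            threshold_crossing(s1, "dp_obs_mean", thr))
})

test_that("one-at-a-time sensitivities behave physically", {
  oat <- parameter_sensitivity_oat(
    baseline_params(), fraction = 0.1,
    quantities = c("CO", "SBP", "MAP"),
    parameters = c("systemic.arterial.R", "total_blood_volume"))
  expect_true(all(oat$converged))
  up <- function(p) oat[oat$parameter == p & oat$direction == 1, ]
  dn <- function(p) oat[oat$parameter == p & oat$direction == -1, ]
  ## raising the systemic microvascular resistance raises MAP
  expect_gt(up("systemic.arterial.R")$dMAP, 0)
  ## more blood raises output
  expect_gt(up("total_blood_volume")$dCO, 0)
  ## first-order symmetry: opposite perturbations flip the sign
  for (p in unique(oat$parameter)) {
    expect_lt(up(p)$dMAP * dn(p)$dMAP, 0)
    expect_lt(up(p)$dCO * dn(p)$dCO, 0)
  }
})

test_that("older-child profile tolerates a given narrowing better", {
  p10 <- default_parameters("child-10yr")
  b10 <- run_to_periodic_steady_state(
    p10, obstruction_geometry("LVOT", 0.5, D = p10$profile$D_LVOT))
  b2 <- obstructed_beat(0.5)
  expect_lt(mean_obstruction_gradient(b10), mean_obstruction_gradient(b2))
  ## relative CO preservation is at least as good in the older child
  co10 <- cardiac_output(b10) /
    cardiac_output(run_to_periodic_steady_state(p10))
  co2 <- cardiac_output(b2) / cardiac_output(baseline_beat())
  expect_gt(co10, co2 - 0.02)
})
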