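## Closed-loop model building blocks: elastance, pressures, valves, RHS.

test_that("elastance cycles smoothly between Emin and Emax", {
  ch <- chamber_params(Emax = 5, Emin = 0.1, V0 = 2, t_act = 0,
                       tau_sys = 0.4, rise_frac = 0.7)
  T <- 60 / 105
  t <- seq(0, T, length.out = 20001)
  E <- elastance(t, ch, T)
  expect_true(all(E >= ch$Emin - 1e-12 & E <= ch$Emax + 1e-12))
  ## inactive after the activation bump
  expect_equal(elastance(0.45 * T, ch, T), ch$Emin)
  ## Emax attained (once) to fine sampling accuracy
  expect_equal(max(E), ch$Emax, tolerance = 1e-6)
  expect_equal(sum(abs(E - ch$Emax) < 1e-9 * ch$Emax), 1L)
  ## cycle mean strictly between the bounds
  m <- mean(E[-length(E)])
  expect_gt(m, ch$Emin); expect_lt(m, ch$Emax)
  ## periodic
  expect_equal(elastance(t + 3 * T, ch, T), E)
})

test_that("activation offset places atrial contraction before systole", {
  T <- 60 / 105
  atr <- chamber_params(0.4, 0.2, 1, t_act = 0.8, tau_sys = 0.2)
  ## atrial elastance peaks late in the cycle, before the next onset
  t <- seq(0, T, length.out = 5001)
  expect_equal(t[which.max(elastance(t, atr, T))] / T, 0.9, tolerance = 0.01)
})

test_that("chamber pressure is the linear elastance law", {
  expect_identical(chamber_pressure(10, E = 2, V0 = 10), 0)
  expect_identical(chamber_pressure(60, E = 1, V0 = 10), 50)
  expect_identical(chamber_pressure(60, E = 2, V0 = 10),
                   2 * chamber_pressure(60, E = 1, V0 = 10))
})

test_that("valve flow is a continuous diode", {
  expect_identical(valve_flow(-3, 0.01), 0)
  expect_identical(valve_flow(1, 0.01), 100)
  expect_equal(valve_flow(1e-12, 0.01), 0, tolerance = 1e-9)
})

test_that("RHS conserves mass at random states", {
  params <- baseline_params()
  geom <- obstruction_geometry("LVOT", 0.4)
  set.seed(7)
  for (i in 1:1000) {
    V <- setNames(runif(8, 5, 400), c("LA", "LV", "SA", "SV",
                                      "RA", "RV", "PA", "PV"))
    t <- runif(1, 0, params$profile$T)
    d <- circulation_rhs(t, V, params, geom)
    expect_lt(abs(sum(d)), 1e-9)
  }
})

test_that("no obstruction reproduces the baseline system exactly", {
  params <- baseline_params()
  set.seed(11)
  V <- setNames(runif(8, 10, 300), c("LA", "LV", "SA", "SV",
                                     "RA", "RV", "PA", "PV"))
  t <- 0.123
  expect_identical(circulation_rhs(t, V, params),
                   circulation_rhs(t, V, params,
                                   obstruction_geometry("NONE", 0.5)))
  ## a fully open obstructed side is also loss-free
  expect_identical(circulation_rhs(t, V, params),
                   circulation_rhs(t, V, params,
                                   obstruction_geometry("LVOT", 1)))
})

test_that("pressure equilibrium implies a stationary state", {
  params <- baseline_params()
  ## pick a phase where every chamber is inactive (E = Emin), then build
  ## volumes putting all compartments at the same pressure
  T <- params$profile$T
  t <- 0.76 * T
  p_star <- 10
  ch <- params$chambers
  V <- c(LA = ch$LA$V0 + p_star / ch$LA$Emin,
         LV = ch$LV$V0 + p_star / ch$LV$Emin,
         SA = params$systemic$arterial$V0 + p_star * params$systemic$arterial$C,
         SV = params$systemic$venous$V0 + p_star * params$systemic$venous$C,
         RA = ch$RA$V0 + p_star / ch$RA$Emin,
         RV = ch$RV$V0 + p_star / ch$RV$Emin,
         PA = params$pulmonary$arterial$V0 + p_star * params$pulmonary$arterial$C,
         PV = params$pulmonary$venous$V0 + p_star * params$pulmonary$venous$C)
  for (ch_nm in c("LA", "LV", "RA", "RV"))
    expect_equal(elastance(t, params$chambers[[ch_nm]], T),
                 params$chambers[[ch_nm]]$Emin)
  d <- circulation_rhs(t, V, params)
  expect_equal(unname(d), rep(0, 8), tolerance = 1e-12)
})

test_that("integrated volumes are consistent with the RHS", {
  ## finite differences of the dense solution match the RHS at interior
  ## times to solver accuracy
  beat <- baseline_beat()
  params <- beat$params
  idx <- seq(50, length(beat$t) - 50, by = 97)
  dt <- beat$t[2] - beat$t[1]
  scale <- max(abs(beat$flows))
  for (i in idx) {
    fd <- (beat$volumes[i + 1L, ] - beat$volumes[i - 1L, ]) / (2 * dt)
    d <- circulation_rhs(beat$t[i], beat$volumes[i, ], params, beat$geom)
    expect_lt(max(abs(fd - d)), 5e-3 * scale)
  }
})

test_that("shipped parameter sets satisfy their invariants", {
  for (label in shipped_profiles()) {
    p <- default_parameters(label)
    expect_s3_class(p, "circulation_params")
    for (ch in p$chambers) {
      expect_gt(ch$Emin, 0)
      expect_gte(ch$Emax, ch$Emin)
    }
    expect_gt(p$total_blood_volume, 0)
  }
  expect_error(default_parameters("adult-35yr"), "unknown profile")
})

test_that("parameter YAML round-trips exactly", {
  p <- baseline_params()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, tmp)
  p2 <- read_parameters(tmp)
  expect_equal(p2, p)
})
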