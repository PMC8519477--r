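## Shared fixtures: expensive converged runs are computed once per test run
## and cached here.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_opts <- function(...) solver_options(...)

baseline_params <- function() memo("params2yr", default_parameters("child-2yr"))

baseline_beat <- function() memo("baseline_beat",
  run_to_periodic_steady_state(baseline_params()))

## a converged moderately obstructed LVOT beat (r = 0.3), warm-started
obstructed_beat <- function(r = 0.3) memo(paste0("lvot_", r), {
  init <- baseline_beat()$beat_starts
  run_to_periodic_steady_state(
    baseline_params(),
    obstruction_geometry("LVOT", narrowing_ratio = r),
    init = init[nrow(init), ])
})

## full default-grid severity sweeps, shared by acceptance criteria
full_sweep <- function(side) memo(paste0("sweep_", side),
  narrowing_sweep(baseline_params(), side))

## hand-built beat object for analytic quadrature oracles: a flow trace and
## enough structure for cardiac_output() / ejection_window()
synthetic_beat <- function(t, Q, T = max(t), side = "LVOT",
                           narrowing_ratio = 0.5) {
  geom <- obstruction_geometry(side, narrowing_ratio = narrowing_ratio)
  K <- compute_K_obs(geom)
  structure(list(
    t = t, T = T, Q_vot = Q,
    dp_obs = obstruction_dp(K, Q),
    dp_doppler = doppler_dp(Q, geom$A_free),
    geom = geom,
    params = baseline_params()),
    class = "vot_beat")
}
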