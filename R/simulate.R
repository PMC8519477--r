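## Integration to periodic steady state and extraction of a converged beat.

#' Solver options
#'
#' @param rel_tol,abs_tol relative / absolute tolerance of the stiff
#'   integrator (`deSolve::lsoda`); absolute tolerance in mL.
#' @param max_beats maximum number of beats before giving up on periodicity.
#' @param periodicity_tol relative beat-start volume change below which the
#'   limit cycle is declared reached (checked per compartment).
#' @param output_sampling number of sample points for the returned beat;
#'   2000 by default because the trans-obstruction gradient peaks sharply at
#'   severe narrowing.
#' @return a `solver_options` list.
#' @export
solver_options <- function(rel_tol = 1e-6, abs_tol = 1e-8, max_beats = 200L,
                           periodicity_tol = 1e-3, output_sampling = 2000L) {
  stopifnot(rel_tol > 0, abs_tol > 0, max_beats >= 2, periodicity_tol > 0,
            output_sampling >= 16)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_beats = as.integer(max_beats),
                 periodicity_tol = periodicity_tol,
                 output_sampling = as.integer(output_sampling)),
            class = "solver_options")
}

#' Integrate the closed loop to its periodic steady state
#'
#' Integrates beat by beat with an adaptive stiff method (`deSolve::lsoda`)
#' until every compartment's beat-start volume changes by less than
#' `opts$periodicity_tol` (relative) between consecutive beats, then samples
#' the converged beat densely and post-processes pressures, flows and
#' obstruction gradients.  The simulator contains no randomness: identical
#' inputs give identical output.
#'
#' @param params a [circulation_parameters()] object (or a profile label
#'   understood by [default_parameters()]).
#' @param geom an [obstruction_geometry()]; `NULL` means no obstruction.
#' @param opts a [solver_options()].
#' @param init optional named initial volume vector (mL) in state order
#'   `LA, LV, SA, SV, RA, RV, PA, PV`; used for warm starts.  By default the
#'   total blood volume is distributed in fixed physiological proportions.
#'   A supplied init is rescaled so that its sum equals the parameter set's
#'   `total_blood_volume` (which the closed loop then conserves).
#' @return a `vot_beat` object: the converged beat with components
#'   \describe{
#'     \item{t}{uniform time grid spanning one period, s}
#'     \item{volumes}{matrix of compartment volumes, mL}
#'     \item{pressures}{data.frame of compartment pressures, mmHg}
#'     \item{flows}{data.frame of branch flows, mL/s}
#'     \item{Q_vot}{flow through the (possibly obstructed) outflow branch:
#'       aortic for LVOT/NONE, pulmonary for RVOT, mL/s}
#'     \item{dp_obs, dp_doppler}{trans-obstruction and simplified-Bernoulli
#'       gradient traces, mmHg}
#'     \item{beats, beat_starts, periodicity, drift}{convergence diagnostics}
#'   }
#' @export
run_to_periodic_steady_state <- function(params, geom = NULL,
                                         opts = solver_options(),
                                         init = NULL) {
  if (is.character(params)) params <- default_parameters(params)
  stopifnot(inherits(params, "circulation_params"),
            inherits(opts, "solver_options"))
  if (is.null(geom)) geom <- obstruction_geometry("NONE")
  ctx <- .model_context(params, geom)
  T <- ctx$T
  f <- function(t, y, p) list(.rhs_core(t, y, ctx))

  y <- if (is.null(init)) .initial_state(params) else {
    stopifnot(setequal(names(init), .STATE_NAMES), all(init > 0))
    ## the closed loop conserves whatever total the initial state carries,
    ## so a (warm-start) init is rescaled to the parameter set's total
    ## blood volume, which is authoritative
    init <- init[.STATE_NAMES]
    init * (params$total_blood_volume / sum(init))
  }
  starts <- matrix(NA_real_, nrow = opts$max_beats + 1L, ncol = 8L,
                   dimnames = list(NULL, .STATE_NAMES))
  starts[1L, ] <- y
  periodicity <- NA_real_
  converged <- FALSE
  for (b in seq_len(opts$max_beats)) {
    sol <- deSolve::lsoda(y, c(0, T), f, parms = NULL,
                          rtol = opts$rel_tol, atol = opts$abs_tol)
    if (attr(sol, "istate")[1L] < 0)
      stop("stiff solver failed at beat ", b)
    y_new <- sol[nrow(sol), -1L]
    periodicity <- max(abs(y_new - y) / abs(y))
    starts[b + 1L, ] <- y_new
    y <- y_new
    if (periodicity < opts$periodicity_tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "no periodic steady state within %d beats (last beat-start change %.3g, tol %.3g)",
      opts$max_beats, periodicity, opts$periodicity_tol))
  starts <- starts[seq_len(b + 1L), , drop = FALSE]

  times <- seq(0, T, length.out = opts$output_sampling)
  sol <- deSolve::lsoda(y, times, f, parms = NULL,
                        rtol = opts$rel_tol, atol = opts$abs_tol)
  if (attr(sol, "istate")[1L] < 0) stop("stiff solver failed on output beat")
  V <- sol[, -1L, drop = FALSE]
  colnames(V) <- .STATE_NAMES
  s <- .eval_state(times, V, ctx)
  Q_vot <- if (geom$side == "RVOT") s$q$pulm_valve else s$q$aortic
  dp_obs <- obstruction_dp(compute_K_obs(geom), Q_vot)
  dp_dop <- doppler_dp(Q_vot, geom$A_free)

  total <- rowSums(V)
  drift <- max(abs(c(total, rowSums(starts)) - total[1L])) / total[1L]

  structure(list(
    t = times, T = T,
    volumes = V,
    pressures = as.data.frame(s$p),
    flows = as.data.frame(s$q),
    Q_vot = Q_vot, dp_obs = dp_obs, dp_doppler = dp_dop,
    geom = geom, params = params, opts = opts,
    beats = b, beat_starts = starts,
    periodicity = periodicity, drift = drift),
    class = "vot_beat")
}

#' @export
print.vot_beat <- function(x, ...) {
  cat(sprintf(
    "<vot_beat> %s  side=%s r=%.3g  T=%.4g s  converged in %d beats (drift %.2g)\n",
    x$params$profile$label, x$geom$side, x$geom$narrowing_ratio, x$T,
    x$beats, x$drift))
  invisible(x)
}

#' Maximum relative total-volume drift of a trajectory
#'
#' The loop is closed, so the summed compartment volume must stay constant;
#' any drift is integrator error.  Accepts a `vot_beat` (checks the dense
#' beat and all recorded beat starts) or a bare volume matrix with one row
#' per time point.
#'
#' @param trajectory a `vot_beat` or numeric matrix of volumes (mL).
#' @return max over time of `|sum(V(t)) - sum(V(0))| / sum(V(0))`.
#' @export
check_conservation <- function(trajectory) {
  V <- if (inherits(trajectory, "vot_beat"))
    rbind(trajectory$volumes, trajectory$beat_starts)
  else as.matrix(trajectory)
  total <- rowSums(V)
  max(abs(total - total[1L])) / total[1L]
}

#' Export a beat as a tidy (long) data.frame
#'
#' One row per (time, variable): volumes (`V_*`, mL), pressures (`p_*`,
#' mmHg), flows (`Q_*`, mL/s) and the gradient traces (`dp_obs`,
#' `dp_doppler`, mmHg).
#'
#' @param x a `vot_beat`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `time_s`, `variable`, `value`.
#' @export
as.data.frame.vot_beat <- function(x, row.names = NULL, optional = FALSE, ...) {
  wide <- cbind(
    as.data.frame(x$volumes)   |> setNames(paste0("V_", .STATE_NAMES)),
    x$pressures                |> setNames(paste0("p_", names(x$pressures))),
    x$flows                    |> setNames(paste0("Q_", names(x$flows))),
    data.frame(dp_obs = x$dp_obs, dp_doppler = x$dp_doppler))
  data.frame(
    time_s = rep(x$t, times = ncol(wide)),
    variable = rep(names(wide), each = length(x$t)),
    value = unlist(wide, use.names = FALSE))
}
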