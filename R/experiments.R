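## Simulation campaigns: narrowing-ratio sweeps, threshold crossings,
## shape-factor sensitivity, one-at-a-time parameter sensitivity.

#' Default narrowing-ratio grid
#'
#' From wide open (1.0) to near-complete occlusion (0.05) in steps of 0.025,
#' sorted descending; lower ratios produce non-physiological near-zero
#' cardiac output.
#' @return numeric vector of ratios.
#' @export
default_ratio_grid <- function() seq(1, 0.05, by = -0.025)

#' Sweep obstruction severity
#'
#' Runs one converged closed-loop simulation per narrowing ratio and collects
#' the hemodynamic summaries.  Consecutive runs are warm-started from the
#' previous ratio's converged state (the periodic steady state does not
#' depend on the initial condition, so this only saves beats).  Ratios whose
#' simulation fails to converge are reported via a warning and excluded from
#' the table, never silently dropped.
#'
#' @param params a [circulation_parameters()] object or profile label.
#' @param side `"LVOT"` or `"RVOT"`.
#' @param ratios narrowing ratios in `[0.05, 1]`; sorted descending
#'   internally.
#' @param f_shape shape factor >= 1.
#' @param opts [solver_options()].
#' @param warm_start reuse the previous ratio's converged state.
#' @return a `vot_sweep` data.frame: one [summarize_beat()] row per ratio,
#'   sorted by ratio descending.
#' @export
narrowing_sweep <- function(params, side = c("LVOT", "RVOT"),
                            ratios = default_ratio_grid(), f_shape = 1,
                            opts = solver_options(), warm_start = TRUE) {
  if (is.character(params)) params <- default_parameters(params)
  side <- match.arg(side)
  stopifnot(all(ratios >= 0.05 - 1e-12), all(ratios <= 1 + 1e-12))
  ratios <- sort(unique(pmin(ratios, 1)), decreasing = TRUE)
  D <- if (side == "LVOT") params$profile$D_LVOT else params$profile$D_RVOT
  rows <- vector("list", length(ratios))
  failed <- character(0)
  init <- NULL
  for (i in seq_along(ratios)) {
    geom <- obstruction_geometry(side, narrowing_ratio = ratios[i], D = D,
                                 f_shape = f_shape)
    row <- tryCatch({
      beat <- run_to_periodic_steady_state(params, geom, opts, init = init)
      if (warm_start) init <- beat$beat_starts[nrow(beat$beat_starts), ]
      summarize_beat(beat)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      failed <- c(failed, sprintf("ratio %.3g: %s", ratios[i],
                                  conditionMessage(row)))
      init <- NULL
      next
    }
    rows[[i]] <- row
  }
  if (length(failed))
    warning("excluded non-converged ratios:\n  ",
            paste(failed, collapse = "\n  "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("vot_sweep", "data.frame")
  attr(out, "failed") <- failed
  out
}

#' Interpolate the narrowing ratio at which a swept quantity crosses a
#' threshold
#'
#' The swept quantities are monotone in the narrowing ratio (gradients
#' non-increasing, CO non-decreasing), so the crossing is located by
#' monotone piecewise-linear interpolation between the two adjacent grid
#' rows bracketing the threshold.  A threshold at a grid value returns that
#' grid ratio exactly.
#'
#' @param table a `vot_sweep` from [narrowing_sweep()] (one side, one
#'   f_shape).
#' @param quantity column name, e.g. `"dp_obs_mean"`, `"dp_doppler_mean"`,
#'   `"CO"`.
#' @param threshold value in the quantity's units.
#' @return the crossing ratio, or `NA` (with a message attribute) when the
#'   threshold lies outside the swept range.
#' @export
threshold_crossing <- function(table, quantity, threshold) {
  stopifnot(inherits(table, "data.frame"), quantity %in% names(table),
            "narrowing_ratio" %in% names(table))
  tab <- table[order(table$narrowing_ratio), c("narrowing_ratio", quantity)]
  x <- tab[[quantity]]
  r <- tab$narrowing_ratio
  if (threshold < min(x) || threshold > max(x)) {
    out <- NA_real_
    attr(out, "message") <- sprintf(
      "threshold %g outside swept range [%g, %g] of %s",
      threshold, min(x), max(x), quantity)
    return(out)
  }
  hit <- which(abs(x - threshold) == 0)
  if (length(hit)) return(r[hit[1L]])
  ## piecewise-linear inverse; quantity must be monotone along the sweep
  o <- order(x)
  approx(x = x[o], y = r[o], xout = threshold, ties = "ordered")$y
}

#' Shape-factor sensitivity sweep
#'
#' Full factorial sweep over `f_shape` values and narrowing ratios.  A larger
#' shape factor inflates the loss coefficient at fixed narrowing, so for a
#' fixed ratio the mean gradient is non-decreasing in `f_shape`, and any
#' fixed-gradient crossing shifts to a larger ratio.
#'
#' @inheritParams narrowing_sweep
#' @param fshape_values shape factors, all >= 1.
#' @return a `vot_sweep` data.frame with one row per (f_shape, ratio).
#' @export
fshape_sensitivity <- function(params, side = c("LVOT", "RVOT"),
                               fshape_values = c(1, 1.5, 2),
                               ratios = default_ratio_grid(),
                               opts = solver_options()) {
  stopifnot(all(fshape_values >= 1))
  out <- do.call(rbind, lapply(fshape_values, function(fs)
    narrowing_sweep(params, side, ratios, f_shape = fs, opts = opts)))
  rownames(out) <- NULL
  class(out) <- c("vot_sweep", "data.frame")
  out
}

## Scalar parameters addressed by path for the OAT sensitivity analysis.
.oat_parameter_paths <- function(params) {
  paths <- c(
    as.vector(outer(c("LA", "LV", "RA", "RV"),
                    c("Emax", "Emin"),
                    function(a, b) paste("chambers", a, b, sep = "."))),
    paste0("valves.", c("R_mv", "R_av", "R_tv", "R_pv")),
    as.vector(outer(c("systemic", "pulmonary"),
                    as.vector(outer(c("arterial", "venous"), c("R", "C"),
                                    paste, sep = ".")),
                    paste, sep = ".")),
    "total_blood_volume")
  paths
}

.get_path <- function(params, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) params <- params[[k]]
  params
}

.set_path <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), keys,
                 accumulate = FALSE, init = quote(params))
  eval(call("<-", expr, value))
  params
}

#' One-at-a-time parameter sensitivity
#'
#' Perturbs each scalar model parameter by `+/- fraction` (relative), re-runs
#' the simulation, and reports the relative change of the requested summary
#' quantities.  The baseline run is computed once and reused.  Perturbed runs
#' that fail to converge are reported in the output rather than raising.
#'
#' @param params a [circulation_parameters()] object or profile label.
#' @param fraction relative perturbation in `(0, 0.5]`.
#' @param quantities summary column names to report.
#' @param parameters parameter paths to perturb (default: all scalar
#'   resistances, compliances, elastances and the total blood volume).
#' @param geom obstruction applied during the analysis (default none).
#' @param opts [solver_options()].
#' @return data.frame with one row per (parameter, direction): the perturbed
#'   value and the relative change `d<quantity>` of each quantity.
#' @export
parameter_sensitivity_oat <- function(params, fraction = 0.1,
                                      quantities = c("CO", "SBP",
                                                     "dp_obs_mean"),
                                      parameters = NULL,
                                      geom = NULL,
                                      opts = solver_options()) {
  if (is.character(params)) params <- default_parameters(params)
  stopifnot(fraction > 0, fraction <= 0.5)
  if (is.null(parameters)) parameters <- .oat_parameter_paths(params)
  base_beat <- run_to_periodic_steady_state(params, geom, opts)
  base <- summarize_beat(base_beat)
  stopifnot(all(quantities %in% names(base)))
  init <- base_beat$beat_starts[nrow(base_beat$beat_starts), ]
  rows <- list()
  for (path in parameters) {
    v0 <- .get_path(params, path)
    for (dir in c(+1, -1)) {
      pert <- .set_path(params, path, v0 * (1 + dir * fraction))
      res <- tryCatch(
        summarize_beat(run_to_periodic_steady_state(pert, geom, opts,
                                                    init = init)),
        error = function(e) e)
      row <- data.frame(parameter = path, direction = dir,
                        value = v0 * (1 + dir * fraction),
                        converged = !inherits(res, "error"))
      for (q in quantities)
        row[[paste0("d", q)]] <- if (inherits(res, "error")) NA_real_ else
          if (abs(base[[q]]) < 1e-12) res[[q]] - base[[q]] else
            (res[[q]] - base[[q]]) / base[[q]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base
  out
}
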