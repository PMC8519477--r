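## Clinical indices from a converged beat: cardiac output, ejection window,
## mean/peak trans-obstruction and Doppler gradients, pressure summaries,
## and validation against pediatric reference ranges.

.EJECT_EPS <- 1e-9   # mL/s: flow threshold defining the ejection window

#' Cardiac output of a converged beat
#'
#' Time average of the ventricular outflow over one period,
#' `CO = (1/T) integral Q dt`, by trapezoidal quadrature on the dense grid,
#' converted to L/min.  The flow used is the branch carrying the obstruction
#' (aortic for LVOT or no obstruction, pulmonary for RVOT); at periodic
#' steady state the two branch means coincide.
#'
#' @param beat a `vot_beat` from [run_to_periodic_steady_state()].
#' @return cardiac output, L/min.
#' @export
cardiac_output <- function(beat) {
  stopifnot(inherits(beat, "vot_beat"))
  (pracma::trapz(beat$t, beat$Q_vot) / beat$T) * 60 / 1000
}

#' Ejection window of a beat
#'
#' Maximal contiguous interval of forward flow (`Q > 1e-9` mL/s) through the
#' ventricular outflow branch.  The diode valve law makes the flow exactly
#' zero outside ejection, so the window is well defined up to one sample
#' step.  A beat with no ejection at all signals circulatory collapse and is
#' reported as an error; more than one contiguous window per beat violates
#' the single-ejection assumption and is likewise an error.  If the valve
#' never closes (under a very severe obstruction the distal pressure can
#' collapse below the ventricular diastolic pressure, leaving a diastolic
#' trickle), the single window spans the whole period.
#'
#' Ejection may wrap around the periodic beat boundary (ventricular
#' activation starts at phase 0, so ejection typically starts slightly after
#' `t = 0`); the window is identified on the periodic extension.
#'
#' The window boundaries are refined below the sampling step by linearly
#' extrapolating the flow's zero crossing from the two adjacent samples, so
#' the ejection period converges at second order in the output sampling.
#'
#' @param beat a `vot_beat`.
#' @return list with `t_start`, `t_end` (s, possibly beyond `T` when the
#'   window wraps the beat boundary), `T_e = t_end - t_start`, the index set
#'   `idx` of samples inside the window, the time `t_first_sample` of the
#'   first of them, and `full` (`TRUE` in the never-closing trickle regime).
#' @export
ejection_window <- function(beat) {
  stopifnot(inherits(beat, "vot_beat"))
  q <- beat$Q_vot
  n <- length(q)
  ## drop the duplicated period endpoint; treat the m samples as circular
  op <- (q > .EJECT_EPS)[-n]
  m <- n - 1L
  if (!any(op)) stop("no ejection: outflow never exceeds ", .EJECT_EPS,
                     " mL/s (circulatory collapse)")
  ## under a very severe obstruction the distal arterial pressure collapses
  ## below the ventricular diastolic pressure and the diode never closes: a
  ## trickle flows all cycle and the single contiguous window is the whole
  ## period
  if (all(op))
    return(list(t_start = 0, t_end = beat$T, T_e = beat$T, idx = seq_len(m),
                t_first_sample = 0, full = TRUE))
  opens <- which(op & !op[c(m, seq_len(m - 1L))])   # closed -> open edges
  if (length(opens) > 1L)
    stop("multiple distinct ejection windows in one beat (",
         length(opens), " found): single-ejection assumption violated")
  len <- 0L
  while (op[(opens - 1L + len) %% m + 1L] && len < m) len <- len + 1L
  dt <- beat$T / m
  idx <- (opens - 1L + seq_len(len) - 1L) %% m + 1L  # circular sample indices
  qq <- q[idx]
  t1 <- beat$t[opens]                                # first open sample
  ## sub-sample valve opening/closure: the flow leaves/returns to zero
  ## between samples; extrapolate its zero crossing linearly from the two
  ## adjacent window samples (falls back to half a step for degenerate
  ## traces), making T_e second-order accurate in the sampling step
  t_open <- if (len >= 3L && qq[2L] > qq[1L])
    max(t1 - dt, t1 - dt * qq[1L] / (qq[2L] - qq[1L])) else t1 - dt / 2
  t_last <- t1 + (len - 1L) * dt
  t_close <- if (len >= 3L && qq[len - 1L] > qq[len])
    min(t_last + dt, t_last + dt * qq[len] / (qq[len - 1L] - qq[len])) else
      t_last + dt / 2
  if (t_open < 0) {                                  # keep times in [0, 2T)
    t_open <- t_open + beat$T; t1 <- t1 + beat$T; t_close <- t_close + beat$T
  }
  list(t_start = t_open, t_end = t_close, T_e = t_close - t_open,
       idx = idx, t_first_sample = t1, full = FALSE)
}

## Mean of a periodic trace over the ejection window, handling wrap-around
## and the sub-sample window edges (where every ejection-gated trace — flow
## and the gradients derived from it — vanishes, so the edge contributions
## are triangles).
.mean_over_ejection <- function(beat, x) {
  ew <- ejection_window(beat)
  if (ew$full) return(pracma::trapz(beat$t, x) / beat$T)
  xx <- x[ew$idx]
  len <- length(ew$idx)
  dt <- beat$T / (length(beat$t) - 1L)
  ts <- ew$t_first_sample + (seq_len(len) - 1L) * dt
  area <- pracma::trapz(ts, xx) +
    0.5 * xx[1L] * (ts[1L] - ew$t_start) +
    0.5 * xx[len] * (ew$t_end - ts[len])
  area / ew$T_e
}

#' Mean trans-obstruction gradient over the ejection period
#'
#' `(1/T_e) integral dp_obs dt` over the ejection window.
#'
#' @param beat a `vot_beat`.
#' @return mmHg.
#' @export
mean_obstruction_gradient <- function(beat) {
  stopifnot(inherits(beat, "vot_beat"))
  if (beat$geom$side == "NONE") return(0)
  .mean_over_ejection(beat, beat$dp_obs)
}

#' Peak trans-obstruction gradient over the beat
#'
#' @param beat a `vot_beat`.
#' @return mmHg; always >= the mean gradient.
#' @export
peak_obstruction_gradient <- function(beat) {
  stopifnot(inherits(beat, "vot_beat"))
  max(beat$dp_obs)
}

#' Mean and peak Doppler (simplified Bernoulli) gradient
#'
#' The pointwise gradient `4 V^2` (V the velocity at the minimum flow area,
#' m/s) averaged over the ejection window and maximized over the beat.  With
#' no obstruction the value is still finite: it is the gradient a Doppler
#' exam would infer from the velocity through the open conduit.
#'
#' @param beat a `vot_beat`.
#' @return named numeric `c(mean =, peak =)`, mmHg.
#' @export
doppler_summary <- function(beat) {
  stopifnot(inherits(beat, "vot_beat"))
  c(mean = .mean_over_ejection(beat, beat$dp_doppler),
    peak = max(beat$dp_doppler))
}

#' Hemodynamic summary of a converged beat
#'
#' One row with the clinical indices used for validation and severity
#' sweeps.  Definitions:
#' \describe{
#'   \item{CO}{cardiac output, L/min ([cardiac_output()]).}
#'   \item{SBP, DBP}{max/min of the systemic arterial pressure trace, mmHg.}
#'   \item{MAP}{time average of systemic arterial pressure, mmHg.}
#'   \item{SVR}{(MAP - mean p_RA) / CO with CO in mL/s, mmHg s/mL.}
#'   \item{p_LA_mean, p_RA_mean}{mean atrial pressures, mmHg.}
#'   \item{p_LV_sys, p_RV_sys}{peak ventricular pressures, mmHg.}
#'   \item{p_LV_dia, p_RV_dia}{end-diastolic ventricular pressures (at
#'     ventricular activation onset), mmHg.}
#'   \item{p_PuA_sys, p_PuA_dia}{max/min pulmonary arterial pressure, mmHg.}
#'   \item{dp_obs_mean, dp_obs_peak}{recovered trans-obstruction gradient,
#'     mmHg.}
#'   \item{dp_doppler_mean, dp_doppler_peak}{pre-recovery gradient, mmHg.}
#'   \item{T_e}{ejection period, s.}
#'   \item{dp_valve_mean}{mean semilunar-valve drop `R_v Q` over ejection on
#'     the outflow branch, mmHg.}
#'   \item{Q_peak}{peak ventricular outflow, mL/s.}
#' }
#'
#' @param beat a `vot_beat`.
#' @param params ignored (the beat carries its parameters); kept for call
#'   symmetry.
#' @return a one-row `data.frame` (class `vot_summary`).
#' @export
summarize_beat <- function(beat, params = beat$params) {
  stopifnot(inherits(beat, "vot_beat"))
  p <- beat$pressures
  t <- beat$t
  co <- cardiac_output(beat)
  ew <- ejection_window(beat)
  map <- pracma::trapz(t, p$SA) / beat$T
  p_ra <- pracma::trapz(t, p$RA) / beat$T
  p_la <- pracma::trapz(t, p$LA) / beat$T
  r_semilunar <- if (beat$geom$side == "RVOT") params$valves$R_pv else
    params$valves$R_av
  dop <- doppler_summary(beat)
  out <- data.frame(
    side = beat$geom$side,
    narrowing_ratio = beat$geom$narrowing_ratio,
    f_shape = beat$geom$f_shape,
    CO = co,
    SBP = max(p$SA), DBP = min(p$SA), MAP = map,
    SVR = (map - p_ra) / (co * 1000 / 60),
    p_LA_mean = p_la, p_RA_mean = p_ra,
    p_LV_sys = max(p$LV), p_LV_dia = p$LV[1L],
    p_RV_sys = max(p$RV), p_RV_dia = p$RV[1L],
    p_PuA_sys = max(p$PA), p_PuA_dia = min(p$PA),
    dp_obs_mean = mean_obstruction_gradient(beat),
    dp_obs_peak = peak_obstruction_gradient(beat),
    dp_doppler_mean = unname(dop["mean"]),
    dp_doppler_peak = unname(dop["peak"]),
    T_e = ew$T_e,
    dp_valve_mean = r_semilunar * .mean_over_ejection(beat, beat$Q_vot),
    Q_peak = max(beat$Q_vot))
  class(out) <- c("vot_summary", "data.frame")
  out
}

#' Pediatric reference ranges for the baseline simulation
#'
#' Literature physiological ranges for a healthy ~2-year-old child, used to
#' validate the unobstructed model: systemic vascular resistance, arterial
#' pressures, chamber and pulmonary pressures, and cardiac output.
#'
#' @return data.frame with columns `quantity`, `low`, `high`, `unit`.
#' @export
reference_ranges <- function() {
  data.frame(
    quantity = c("SVR", "SBP", "DBP", "p_RV_sys", "p_RV_dia", "p_PuA_sys",
                 "p_PuA_dia", "p_LA_mean", "p_LV_sys", "p_LV_dia",
                 "p_RA_mean", "CO"),
    low  = c(1.5, 90, 65, 15, 3, 15, 10, 5, 90, 7, 2, 1.3),
    high = c(2.1, 110, 75, 23, 7, 23, 16, 10, 110, 9, 6, 2.7),
    unit = c("mmHg.s/mL", rep("mmHg", 10L), "L/min"))
}

#' Compare a hemodynamic summary with reference ranges
#'
#' Flags each quantity as inside or outside its `[low, high]` band.  Never
#' raises on failure: the report is the result.  (In the shipped calibration
#' a few diastolic chamber pressures sit at or slightly outside the
#' literature band, as is typical for simple elastance models.)
#'
#' @param summary a `vot_summary` row from [summarize_beat()].
#' @param ranges a data.frame as from [reference_ranges()].
#' @return the `ranges` data.frame with added columns `value` and `pass`.
#' @export
validate_against_reference <- function(summary, ranges = reference_ranges()) {
  stopifnot(inherits(summary, "data.frame"),
            all(c("quantity", "low", "high") %in% names(ranges)))
  stopifnot(all(ranges$low <= ranges$high))
  ranges$value <- vapply(ranges$quantity, function(q) {
    if (!q %in% names(summary)) NA_real_ else as.numeric(summary[[q]][1L])
  }, numeric(1))
  ranges$pass <- !is.na(ranges$value) &
    ranges$value >= ranges$low & ranges$value <= ranges$high
  ranges
}
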