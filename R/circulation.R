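## Closed-loop 0D circulation: 8 volume states
##   LA, LV, SA (systemic arterial), SV (systemic venous),
##   RA, RV, PA (pulmonary arterial), PV (pulmonary venous).
## Chambers follow the time-varying elastance law p = E(t) (V - V0); vascular
## compartments are linear capacitors p = (V - V0)/C with resistive outflow.
## Valves are resistive diodes; the semilunar valve on the obstructed side
## carries the quadratic orifice loss in series.

.STATE_NAMES <- c("LA", "LV", "SA", "SV", "RA", "RV", "PA", "PV")

## Raised-cosine activation bump: 0 outside [0, tau), rises over rise*tau,
## relaxes over (1-rise)*tau, continuously differentiable everywhere (zero
## slope at 0, at the peak and at tau).  Without flow inertance the ejection
## window is confined to the rising limb, so ventricles use a slow rise and
## a fast relaxation (rise > 0.5), which reproduces the physiological
## ejection duration and flow peak.
.activation <- function(phi, tau, rise = 0.5) {
  a <- numeric(length(phi))
  up <- phi >= 0 & phi < rise * tau
  dn <- phi >= rise * tau & phi < tau
  a[up] <- 0.5 * (1 - cos(pi * phi[up] / (rise * tau)))
  a[dn] <- 0.5 * (1 + cos(pi * (phi[dn] - rise * tau) / ((1 - rise) * tau)))
  a
}

#' Time-varying chamber elastance
#'
#' Periodic elastance `E(t)` cycling between `Emin` and `Emax` with a smooth
#' (C^1) raised-cosine activation of duration `tau_sys * T` starting at
#' `t_act * T`.  `E` attains `Emax` exactly once per cycle, halfway through
#' the activation bump.
#'
#' @param t time, s (vectorized; any real value, reduced modulo the cycle).
#' @param chamber a [chamber_params()].
#' @param T cycle length, s.
#' @return elastance in mmHg/mL, same length as `t`.
#' @export
elastance <- function(t, chamber, T) {
  stopifnot(inherits(chamber, "chamber_params"), T > 0)
  phi <- ((t / T) - chamber$t_act) %% 1
  chamber$Emin + (chamber$Emax - chamber$Emin) *
    .activation(phi, chamber$tau_sys, chamber$rise_frac)
}

#' Chamber pressure from the elastance law
#'
#' @param V chamber volume, mL.
#' @param E instantaneous elastance, mmHg/mL.
#' @param V0 unstressed volume, mL.
#' @return pressure `E * (V - V0)` in mmHg.
#' @export
chamber_pressure <- function(V, E, V0) E * (V - V0)

#' Diode valve flow
#'
#' @param dp trans-valvular pressure, mmHg (vectorized).
#' @param R_v valve resistance, mmHg s/mL.
#' @return forward flow `max(dp, 0)/R_v` in mL/s; never negative.
#' @export
valve_flow <- function(dp, R_v) {
  stopifnot(R_v > 0)
  pmax(dp, 0) / R_v
}

## Flatten params + geometry into a plain environment the integrator's RHS
## can read cheaply (no S3 dispatch inside the ODE loop).
.model_context <- function(params, geom = NULL) {
  stopifnot(inherits(params, "circulation_params"))
  if (is.null(geom)) geom <- obstruction_geometry("NONE")
  stopifnot(inherits(geom, "vot_geometry"))
  K <- compute_K_obs(geom)
  ch <- params$chambers
  cm <- vapply(ch, function(x) c(x$Emax, x$Emin, x$V0, x$t_act, x$tau_sys,
                                 x$rise_frac),
               numeric(6))                      # 6 x 4, cols LA LV RA RV
  list(
    T = params$profile$T,
    cm = cm,
    R_mv = params$valves$R_mv, R_av = params$valves$R_av,
    R_tv = params$valves$R_tv, R_pv = params$valves$R_pv,
    R_SA = params$systemic$arterial$R,  C_SA = params$systemic$arterial$C,
    V0_SA = params$systemic$arterial$V0,
    R_SV = params$systemic$venous$R,    C_SV = params$systemic$venous$C,
    V0_SV = params$systemic$venous$V0,
    R_PA = params$pulmonary$arterial$R, C_PA = params$pulmonary$arterial$C,
    V0_PA = params$pulmonary$arterial$V0,
    R_PV = params$pulmonary$venous$R,   C_PV = params$pulmonary$venous$C,
    V0_PV = params$pulmonary$venous$V0,
    K_lvot = if (geom$side == "LVOT") K else 0,
    K_rvot = if (geom$side == "RVOT") K else 0,
    A_free = geom$A_free,
    side = geom$side)
}

## Elastances of the four chambers at (possibly vector) time t.
.elastances <- function(t, ctx) {
  cm <- ctx$cm
  tt <- t / ctx$T
  e1 <- function(j) {
    phi <- (tt - cm[4, j]) %% 1
    cm[2, j] + (cm[1, j] - cm[2, j]) * .activation(phi, cm[5, j], cm[6, j])
  }
  list(LA = e1(1L), LV = e1(2L), RA = e1(3L), RV = e1(4L))
}

## Pressures and flows at (vector) time t for a matrix of states
## (rows = times, cols = .STATE_NAMES).  Single source of truth shared by the
## scalar RHS and by beat post-processing.
.eval_state <- function(t, V, ctx) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L,
                                   dimnames = list(NULL, .STATE_NAMES))
  E <- .elastances(t, ctx)
  cm <- ctx$cm
  p <- list(
    LA = E$LA * (V[, "LA"] - cm[3, 1L]),
    LV = E$LV * (V[, "LV"] - cm[3, 2L]),
    SA = (V[, "SA"] - ctx$V0_SA) / ctx$C_SA,
    SV = (V[, "SV"] - ctx$V0_SV) / ctx$C_SV,
    RA = E$RA * (V[, "RA"] - cm[3, 3L]),
    RV = E$RV * (V[, "RV"] - cm[3, 4L]),
    PA = (V[, "PA"] - ctx$V0_PA) / ctx$C_PA,
    PV = (V[, "PV"] - ctx$V0_PV) / ctx$C_PV)
  q <- list(
    mitral    = pmax(p$LA - p$LV, 0) / ctx$R_mv,
    aortic    = outflow_from_gradient(p$LV - p$SA, ctx$R_av, ctx$K_lvot),
    systemic  = (p$SA - p$SV) / ctx$R_SA,
    sys_venous = (p$SV - p$RA) / ctx$R_SV,
    tricuspid = pmax(p$RA - p$RV, 0) / ctx$R_tv,
    pulm_valve = outflow_from_gradient(p$RV - p$PA, ctx$R_pv, ctx$K_rvot),
    pulmonary = (p$PA - p$PV) / ctx$R_PA,
    pulm_venous = (p$PV - p$LA) / ctx$R_PV)
  list(p = p, q = q)
}

## Derivative of the 8 volumes; mass-conserving by construction.  Scalar and
## allocation-light: this is the integrator's inner loop.  The algebra is the
## same as .eval_state(); the numerical-consistency test (finite differences
## of integrated volumes vs the RHS) guards the two paths against drifting
## apart.
.rhs_core <- function(t, V, ctx) {
  cm <- ctx$cm
  tt <- t / ctx$T
  E <- numeric(4L)
  for (j in 1:4) {                       # cols: LA LV RA RV
    phi <- (tt - cm[4L, j]) %% 1
    tau <- cm[5L, j]; rise <- cm[6L, j]
    a <- if (phi >= tau) 0 else if (phi < rise * tau)
      0.5 * (1 - cos(pi * phi / (rise * tau)))
    else
      0.5 * (1 + cos(pi * (phi - rise * tau) / ((1 - rise) * tau)))
    E[j] <- cm[2L, j] + (cm[1L, j] - cm[2L, j]) * a
  }
  pLA <- E[1L] * (V[1L] - cm[3, 1L])
  pLV <- E[2L] * (V[2L] - cm[3, 2L])
  pSA <- (V[3L] - ctx$V0_SA) / ctx$C_SA
  pSV <- (V[4L] - ctx$V0_SV) / ctx$C_SV
  pRA <- E[3L] * (V[5L] - cm[3, 3L])
  pRV <- E[4L] * (V[6L] - cm[3, 4L])
  pPA <- (V[7L] - ctx$V0_PA) / ctx$C_PA
  pPV <- (V[8L] - ctx$V0_PV) / ctx$C_PV
  dp_av <- pLV - pSA
  q_av <- if (dp_av <= 0) 0 else if (ctx$K_lvot == 0) dp_av / ctx$R_av else
    (-ctx$R_av + sqrt(ctx$R_av^2 + 4 * ctx$K_lvot * dp_av)) / (2 * ctx$K_lvot)
  dp_pv <- pRV - pPA
  q_pv <- if (dp_pv <= 0) 0 else if (ctx$K_rvot == 0) dp_pv / ctx$R_pv else
    (-ctx$R_pv + sqrt(ctx$R_pv^2 + 4 * ctx$K_rvot * dp_pv)) / (2 * ctx$K_rvot)
  q_mv <- max(pLA - pLV, 0) / ctx$R_mv
  q_tv <- max(pRA - pRV, 0) / ctx$R_tv
  q_sys <- (pSA - pSV) / ctx$R_SA
  q_sv  <- (pSV - pRA) / ctx$R_SV
  q_pul <- (pPA - pPV) / ctx$R_PA
  q_pvn <- (pPV - pLA) / ctx$R_PV
  d <- c(q_pvn - q_mv,    # LA
         q_mv - q_av,     # LV
         q_av - q_sys,    # SA
         q_sys - q_sv,    # SV
         q_sv - q_tv,     # RA
         q_tv - q_pv,     # RV
         q_pv - q_pul,    # PA
         q_pul - q_pvn)   # PV
  if (any(!is.finite(d)))
    stop("non-finite derivative: corrupt state or parameters at t = ", t)
  d
}

#' Right-hand side of the closed-loop ODE system
#'
#' Volume derivatives `dV/dt` (mL/s) of the 8 compartments at time `t`.
#' Pressures follow from volumes (elastance law for chambers, linear
#' compliance for vessels); flows from pressure differences (diode valves,
#' linear microvascular and venous resistances); each compartment's
#' derivative is inflow minus outflow, so the derivatives sum to zero
#' exactly (closed loop).
#'
#' The obstruction in `geom` is inserted in series with the aortic
#' (`side = "LVOT"`) or pulmonary (`side = "RVOT"`) valve; with
#' `side = "NONE"` both semilunar branches are plain diodes and the system is
#' identical to the unobstructed model.
#'
#' @param t time, s.
#' @param state named numeric vector of compartment volumes, mL, in the order
#'   `LA, LV, SA, SV, RA, RV, PA, PV`.
#' @param params a [circulation_parameters()] object.
#' @param geom an [obstruction_geometry()] (default: none).
#' @return named numeric vector of derivatives, mL/s.
#' @export
circulation_rhs <- function(t, state, params, geom = NULL) {
  ctx <- .model_context(params, geom)
  setNames(.rhs_core(t, state, ctx), .STATE_NAMES)
}

## Initial distribution of total blood volume over the compartments:
## unstressed volumes are filled first, the remaining stressed volume is
## split in fixed physiological proportions (venous pooling dominates).
.STRESSED_FRACTIONS <- c(LA = 0.035, LV = 0.065, SA = 0.16, SV = 0.42,
                         RA = 0.035, RV = 0.065, PA = 0.07, PV = 0.15)

.initial_state <- function(params) {
  ch_v0 <- vapply(params$chambers, `[[`, 0, "V0")   # LA LV RA RV
  vs_v0 <- c(SA = params$systemic$arterial$V0, SV = params$systemic$venous$V0,
             PA = params$pulmonary$arterial$V0, PV = params$pulmonary$venous$V0)
  v0 <- c(LA = ch_v0[["LA"]], LV = ch_v0[["LV"]], vs_v0["SA"], vs_v0["SV"],
          RA = ch_v0[["RA"]], RV = ch_v0[["RV"]], vs_v0["PA"], vs_v0["PV"])
  stressed <- params$total_blood_volume - sum(v0)
  v0[.STATE_NAMES] + stressed * .STRESSED_FRACTIONS[.STATE_NAMES]
}
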