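## Orifice model of the outflow-tract obstruction.
## Clinical units (mmHg, mL, s) everywhere except where noted; the two SI
## conversions (loss coefficient, Doppler velocity) live in this file only.

# Pa.s2/m6 -> mmHg.s2/mL2
.PA_PER_MMHG <- 133.322
.K_SI_TO_CLINICAL <- 1e-12 / .PA_PER_MMHG

.VOT_SIDES <- c("LVOT", "RVOT", "NONE")

## Reference outflow-tract diameters (cm) for the shipped pediatric profile.
.DEFAULT_D <- c(LVOT = 0.9, RVOT = 1.07, NONE = 0.9)

#' Describe a ventricular outflow tract obstruction
#'
#' Geometry of a localized, concentric narrowing in the left or right
#' ventricular outflow tract (VOT), modelled as a circular conduit of diameter
#' `D` partially occluded so that only the fraction `narrowing_ratio` of its
#' cross-sectional area `A = pi (D/2)^2` remains open (`A_free =
#' narrowing_ratio * A`).  The lesion is of negligible length: all loss is
#' concentrated at the orifice.
#'
#' @param side `"LVOT"`, `"RVOT"` or `"NONE"`.  With `"NONE"` the obstruction
#'   contributes zero loss regardless of the other fields (the geometry is
#'   still usable to compute a Doppler velocity through the open conduit).
#' @param narrowing_ratio dimensionless `A_free / A` in (0, 1]; 1 means no
#'   obstruction.
#' @param D conduit (outflow tract) diameter in cm.  Defaults to 0.9 cm for
#'   the LVOT and 1.07 cm for the RVOT of the reference 2-year-old.
#' @param f_shape dimensionless shape factor >= 1 accounting for obstruction
#'   morphology; 1 is an ideal round, annular, concentric orifice.
#' @param rho blood density in kg/m^3 (default 1060).
#'
#' @return An object of class `vot_geometry` with fields `side`, `D`,
#'   `narrowing_ratio`, `f_shape`, `rho` and derived areas `A`, `A_free`
#'   (m^2).
#' @seealso [compute_K_obs()], [obstruction_dp()], [doppler_dp()]
#' @export
#' @examples
#' obstruction_geometry("LVOT", narrowing_ratio = 0.5)
obstruction_geometry <- function(side = c("NONE", "LVOT", "RVOT"),
                                 narrowing_ratio = 1,
                                 D = NULL,
                                 f_shape = 1,
                                 rho = 1060) {
  side <- match.arg(side, .VOT_SIDES)
  if (is.null(D)) D <- unname(.DEFAULT_D[side])
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(narrowing_ratio), length(narrowing_ratio) == 1L,
            is.numeric(f_shape), length(f_shape) == 1L,
            is.numeric(rho), length(rho) == 1L)
  if (D <= 0) stop("conduit diameter D must be > 0 (cm)")
  if (!is.finite(narrowing_ratio) || narrowing_ratio <= 0 || narrowing_ratio > 1)
    stop("narrowing_ratio (A_free/A) must lie in (0, 1], got ", narrowing_ratio)
  if (f_shape < 1) stop("f_shape must be >= 1")
  if (rho <= 0) stop("blood density rho must be > 0 (kg/m^3)")
  A <- pi * (D / 100 / 2)^2                 # m^2
  geom <- list(side = side, D = D, narrowing_ratio = narrowing_ratio,
               f_shape = f_shape, rho = rho,
               A = A, A_free = narrowing_ratio * A)
  class(geom) <- "vot_geometry"
  geom
}

#' @export
print.vot_geometry <- function(x, ...) {
  cat(sprintf(
    "<vot_geometry> side=%s  D=%.3g cm  A_free/A=%.3g  f_shape=%.3g  K_obs=%.4g mmHg.s2/mL2\n",
    x$side, x$D, x$narrowing_ratio, x$f_shape, compute_K_obs(x)))
  invisible(x)
}

#' Quadratic loss coefficient of an obstruction
#'
#' Evaluates the orifice loss coefficient
#' `K_obs = f_shape * (rho/2) * (1/A_free - 1/A)^2` in SI units
#' (Pa s^2/m^6) and converts it to clinical units, mmHg s^2/mL^2, so that the
#' trans-obstruction drop is `dp = K_obs * Q^2` with `Q` in mL/s.
#'
#' `K_obs` is zero iff the conduit is fully open (`narrowing_ratio = 1`) or
#' `side = "NONE"`.
#'
#' @param geom a [obstruction_geometry()] object.
#' @return loss coefficient in mmHg s^2/mL^2 (scalar >= 0).
#' @export
#' @examples
#' compute_K_obs(obstruction_geometry("LVOT", narrowing_ratio = 0.5))
compute_K_obs <- function(geom) {
  stopifnot(inherits(geom, "vot_geometry"))
  if (geom$side == "NONE") return(0)
  k_si <- geom$f_shape * (geom$rho / 2) * (1 / geom$A_free - 1 / geom$A)^2
  k <- k_si * .K_SI_TO_CLINICAL
  if (!is.finite(k)) stop("non-finite loss coefficient: degenerate geometry")
  k
}

#' Instantaneous trans-obstruction pressure gradient
#'
#' `dp_obs = K_obs * Q^2`: the irreversible (post-recovery) pressure drop
#' between the ventricle and the section distal to the obstruction.
#'
#' @param K_obs loss coefficient, mmHg s^2/mL^2 (>= 0).
#' @param Q instantaneous flow rate through the obstruction, mL/s
#'   (vectorized).
#' @return gradient in mmHg, same length as `Q`.
#' @export
obstruction_dp <- function(K_obs, Q) {
  stopifnot(is.numeric(K_obs), length(K_obs) == 1L, K_obs >= 0)
  K_obs * Q^2
}

#' Doppler (simplified Bernoulli) gradient
#'
#' The gradient a Doppler echocardiogram would report from the jet velocity at
#' the minimum flow area: `dp = 4 * V^2` with `V = Q / A_free` in m/s and the
#' result in mmHg (the clinical convention).  This "pre-recovery" gradient
#' does not include pressure recovery and is therefore >= the recovered
#' gradient [obstruction_dp()] when `f_shape = 1`.
#'
#' @param Q flow rate, mL/s (vectorized).
#' @param A_free minimum open area, m^2.
#' @return gradient in mmHg.
#' @export
doppler_dp <- function(Q, A_free) {
  stopifnot(is.numeric(A_free), length(A_free) == 1L)
  if (!is.finite(A_free) || A_free <= 0) stop("A_free must be > 0 (m^2)")
  v <- (Q * 1e-6) / A_free                  # m/s
  4 * v^2
}

#' Branch flow from a driving pressure across valve plus obstruction
#'
#' The ventricular outflow branch is a resistive valve (`dp_v = R_v * Q`) in
#' series with the quadratic orifice loss (`dp_obs = K_obs * Q^2`), gated as a
#' diode: no backflow.  For a driving pressure `dp > 0` the flow is the unique
#' non-negative root of `K_obs Q^2 + R_v Q = dp`; for `dp <= 0` the flow is
#' zero.
#'
#' @param dp driving pressure ventricle minus artery, mmHg (vectorized).
#' @param R_v valve resistance, mmHg s/mL (> 0).
#' @param K_obs obstruction loss coefficient, mmHg s^2/mL^2 (>= 0).
#' @return flow in mL/s (>= 0).
#' @export
#' @examples
#' outflow_from_gradient(10, R_v = 0.01, K_obs = 0.001)
outflow_from_gradient <- function(dp, R_v, K_obs = 0) {
  stopifnot(is.numeric(R_v), length(R_v) == 1L, R_v > 0,
            is.numeric(K_obs), length(K_obs) == 1L, K_obs >= 0)
  dpp <- pmax(dp, 0)
  if (K_obs == 0) return(dpp / R_v)
  (-R_v + sqrt(R_v^2 + 4 * K_obs * dpp)) / (2 * K_obs)
}

#' Conduit diameter implied by a peak flow and peak velocity
#'
#' Closed-form worked example used for model validation: a circular conduit
#' carrying peak flow `Q` at peak velocity `V` has area `A = Q/V` and diameter
#' `D = 2 sqrt(A/pi)`.
#'
#' @param Q_peak peak flow rate, mL/s.
#' @param V_peak peak velocity, cm/s.
#' @return diameter in cm.
#' @export
#' @examples
#' diameter_from_flow_velocity(200, 150)  # ~1.3 cm
diameter_from_flow_velocity <- function(Q_peak, V_peak) {
  stopifnot(Q_peak > 0, V_peak > 0)
  A_cm2 <- Q_peak / V_peak
  2 * sqrt(A_cm2 / pi)
}
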