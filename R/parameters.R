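## Parameter containers for the closed-loop 0D circulation.
##
## All resistances in mmHg.s/mL, compliances in mL/mmHg, elastances in
## mmHg/mL, volumes in mL.  Timing parameters (activation onset, systolic
## duration) are fractions of the cardiac cycle so the same chamber
## description works at any heart rate.

#' Heart chamber (time-varying elastance) parameters
#'
#' @param Emax end-systolic elastance, mmHg/mL.
#' @param Emin diastolic elastance, mmHg/mL.
#' @param V0 unstressed volume, mL.
#' @param t_act activation onset as a fraction of the cycle (ventricles start
#'   at 0; atrial contraction is placed late in the cycle so it precedes
#'   ventricular systole).
#' @param tau_sys duration of the activation bump as a fraction of the cycle.
#' @param rise_frac fraction of the activation bump spent contracting
#'   (reaching `Emax`); the remaining `1 - rise_frac` is relaxation.  In a
#'   purely resistive outflow branch (no inertance) ejection is confined to
#'   the rising limb, so ventricles use `rise_frac > 0.5` to reproduce the
#'   physiological ejection duration.
#' @return a `chamber_params` list.
#' @export
chamber_params <- function(Emax, Emin, V0, t_act, tau_sys, rise_frac = 0.5) {
  stopifnot(Emin > 0, Emax >= Emin, V0 >= 0,
            t_act >= 0, t_act < 1, tau_sys > 0, tau_sys < 1,
            rise_frac > 0, rise_frac < 1)
  structure(list(Emax = Emax, Emin = Emin, V0 = V0,
                 t_act = t_act, tau_sys = tau_sys, rise_frac = rise_frac),
            class = "chamber_params")
}

#' Vascular compartment parameters
#'
#' A lumped compliant compartment with a resistive outflow: pressure
#' `p = (V - V0)/C`, outflow through `R` into the next compartment.  The
#' arterial compartments' `R` is the microvascular bed; the venous
#' compartments' `R` is the venous return resistance into the atrium.
#'
#' @param R outflow resistance, mmHg s/mL.
#' @param C compliance, mL/mmHg.
#' @param V0 unstressed volume, mL.
#' @return a `vascular_params` list.
#' @export
vascular_params <- function(R, C, V0) {
  stopifnot(R > 0, C > 0, V0 >= 0)
  structure(list(R = R, C = C, V0 = V0), class = "vascular_params")
}

#' Valve resistances
#'
#' One resistance per valve, mmHg s/mL.  Valves are on/off diodes: forward
#' flow `Q = dp/R_v` when the trans-valvular pressure `dp > 0`, else zero.
#' Aortic and pulmonary resistances are small enough that the baseline mean
#' trans-valvular drop stays within 1-2 mmHg and never confounds the
#' obstruction gradient.
#'
#' @param R_mv,R_av,R_tv,R_pv mitral, aortic, tricuspid, pulmonary valve
#'   resistances.
#' @return a `valve_params` list.
#' @export
valve_params <- function(R_mv, R_av, R_tv, R_pv) {
  stopifnot(R_mv > 0, R_av > 0, R_tv > 0, R_pv > 0)
  structure(list(R_mv = R_mv, R_av = R_av, R_tv = R_tv, R_pv = R_pv),
            class = "valve_params")
}

#' Subject profile
#'
#' @param HR heart rate, bpm.
#' @param BSA body surface area, m^2.
#' @param BM body mass, kg.
#' @param D_LVOT,D_RVOT left/right ventricular outflow tract diameters, cm.
#' @param label free-text profile name.
#' @return a `subject_profile` list; the cycle length `T = 60/HR` s is
#'   derived.
#' @export
subject_profile <- function(HR, BSA, BM, D_LVOT, D_RVOT, label = "subject") {
  stopifnot(HR > 0, BSA > 0, BM > 0, D_LVOT > 0, D_RVOT > 0)
  structure(list(HR = HR, BSA = BSA, BM = BM,
                 D_LVOT = D_LVOT, D_RVOT = D_RVOT,
                 T = 60 / HR, label = as.character(label)),
            class = "subject_profile")
}

.CHAMBERS <- c("LA", "LV", "RA", "RV")

#' Full closed-loop parameter set
#'
#' @param profile a [subject_profile()].
#' @param chambers named list `LA`, `LV`, `RA`, `RV` of [chamber_params()].
#' @param valves a [valve_params()].
#' @param systemic,pulmonary named lists `arterial`, `venous` of
#'   [vascular_params()].
#' @param total_blood_volume mL; distributed over the 8 compartments at
#'   initialization.
#' @return a `circulation_params` object.
#' @export
circulation_parameters <- function(profile, chambers, valves,
                                   systemic, pulmonary, total_blood_volume) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(valves, "valve_params"),
            setequal(names(chambers), .CHAMBERS),
            setequal(names(systemic), c("arterial", "venous")),
            setequal(names(pulmonary), c("arterial", "venous")),
            total_blood_volume > 0)
  for (ch in chambers) stopifnot(inherits(ch, "chamber_params"))
  for (v in c(systemic, pulmonary)) stopifnot(inherits(v, "vascular_params"))
  v0_total <- sum(vapply(chambers, `[[`, 0, "V0")) +
    sum(vapply(c(systemic, pulmonary), `[[`, 0, "V0"))
  if (total_blood_volume <= v0_total)
    stop("total_blood_volume must exceed the summed unstressed volumes (",
         round(v0_total), " mL)")
  structure(list(profile = profile,
                 chambers = chambers[.CHAMBERS],
                 valves = valves,
                 systemic = systemic, pulmonary = pulmonary,
                 total_blood_volume = total_blood_volume),
            class = "circulation_params")
}

#' @export
print.circulation_params <- function(x, ...) {
  cat(sprintf("<circulation_params> %s: HR %g bpm, BSA %g m2, blood volume %g mL\n",
              x$profile$label, x$profile$HR, x$profile$BSA,
              x$total_blood_volume))
  invisible(x)
}

#' Shipped subject parameterizations
#'
#' Returns the frozen, calibrated parameter set for one of the profiles
#' shipped with the package:
#'
#' * `"child-2yr"` — the reference 2-year-old (HR 105 bpm, BSA 0.55 m^2,
#'   BM 12 kg, D_LVOT 0.9 cm, D_RVOT 1.07 cm), calibrated so the baseline
#'   (no-obstruction) simulation reproduces pediatric reference hemodynamics
#'   (CO about 2.2 L/min, SBP/DBP about 93/64 mmHg, SVR about 2 mmHg s/mL,
#'   peak aortic flow about 200 mL/s).  See `scripts/calibrate.R` in the
#'   source repository for how the set was produced.
#' * `"child-10yr"` — an experimental 10-year-old comparison profile obtained
#'   by allometric (BSA-based) scaling of the 2-year-old set; not validated
#'   against an equivalent reference table.
#'
#' Parameter files live under `system.file("extdata", package = "votsim")` as
#' YAML with explicit units in every field name.
#'
#' @param profile profile label (or a path to a YAML parameter file following
#'   the same schema).
#' @return a [circulation_parameters()] object.
#' @export
default_parameters <- function(profile = "child-2yr") {
  if (inherits(profile, "subject_profile"))
    stop("default_parameters() takes a profile label; ",
         "build custom sets with circulation_parameters()")
  stopifnot(is.character(profile), length(profile) == 1L)
  path <- if (file.exists(profile) && grepl("\\.ya?ml$", profile)) {
    profile
  } else {
    p <- system.file("extdata", paste0(profile, ".yaml"), package = "votsim")
    if (!nzchar(p))
      stop("unknown profile '", profile, "'; shipped profiles: ",
           paste(shipped_profiles(), collapse = ", "))
    p
  }
  read_parameters(path)
}

#' @rdname default_parameters
#' @export
shipped_profiles <- function() {
  sub("\\.yaml$", "", list.files(system.file("extdata", package = "votsim"),
                                 pattern = "^child-.*\\.yaml$"))
}

#' Read / write a parameter set as YAML
#'
#' The schema mirrors [circulation_parameters()]; every field name carries
#' its unit.  `write_parameters()` followed by `read_parameters()`
#' round-trips exactly (values are serialized at full precision).
#'
#' @param path YAML file path.
#' @return `read_parameters()` returns a `circulation_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("profile", "chambers", "valves", "systemic", "pulmonary",
            "total_blood_volume_mL")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("parameter file missing fields: ",
                         paste(miss, collapse = ", "))
  pr <- y$profile
  profile <- subject_profile(HR = pr$HR_bpm, BSA = pr$BSA_m2, BM = pr$BM_kg,
                             D_LVOT = pr$D_LVOT_cm, D_RVOT = pr$D_RVOT_cm,
                             label = pr$label)
  chambers <- lapply(y$chambers[.CHAMBERS], function(ch)
    chamber_params(Emax = ch$Emax_mmHg_per_mL, Emin = ch$Emin_mmHg_per_mL,
                   V0 = ch$V0_mL, t_act = ch$t_act_frac,
                   tau_sys = ch$tau_sys_frac,
                   rise_frac = if (is.null(ch$rise_frac)) 0.5 else
                     ch$rise_frac))
  valves <- valve_params(R_mv = y$valves$R_mv_mmHg_s_per_mL,
                         R_av = y$valves$R_av_mmHg_s_per_mL,
                         R_tv = y$valves$R_tv_mmHg_s_per_mL,
                         R_pv = y$valves$R_pv_mmHg_s_per_mL)
  vasc <- function(v) vascular_params(R = v$R_mmHg_s_per_mL,
                                      C = v$C_mL_per_mmHg, V0 = v$V0_mL)
  circulation_parameters(
    profile = profile, chambers = chambers, valves = valves,
    systemic = lapply(y$systemic[c("arterial", "venous")], vasc),
    pulmonary = lapply(y$pulmonary[c("arterial", "venous")], vasc),
    total_blood_volume = y$total_blood_volume_mL)
}

#' @rdname read_parameters
#' @param params a `circulation_params` object.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "circulation_params"))
  pr <- params$profile
  ch <- lapply(params$chambers, function(c.)
    list(Emax_mmHg_per_mL = c.$Emax, Emin_mmHg_per_mL = c.$Emin,
         V0_mL = c.$V0, t_act_frac = c.$t_act, tau_sys_frac = c.$tau_sys,
         rise_frac = c.$rise_frac))
  vasc <- function(v) list(R_mmHg_s_per_mL = v$R, C_mL_per_mmHg = v$C,
                           V0_mL = v$V0)
  y <- list(
    profile = list(label = pr$label, HR_bpm = pr$HR, BSA_m2 = pr$BSA,
                   BM_kg = pr$BM, D_LVOT_cm = pr$D_LVOT,
                   D_RVOT_cm = pr$D_RVOT),
    chambers = ch,
    valves = list(R_mv_mmHg_s_per_mL = params$valves$R_mv,
                  R_av_mmHg_s_per_mL = params$valves$R_av,
                  R_tv_mmHg_s_per_mL = params$valves$R_tv,
                  R_pv_mmHg_s_per_mL = params$valves$R_pv),
    systemic = lapply(params$systemic, vasc),
    pulmonary = lapply(params$pulmonary, vasc),
    total_blood_volume_mL = params$total_blood_volume)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
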