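---
title: "Modelling ventricular outflow tract obstruction with votsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventricular outflow tract obstruction with votsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Obstruction of the left or right ventricular outflow tract (LVOT/RVOT) — a
congenital stenosis, a subvalvular membrane, or a tumour mass near the
semilunar valve — forces the ventricle to work against a localized pressure
loss. Clinically its severity is graded by the trans-obstruction pressure
gradient and by its effect on cardiac output (CO), but the gradient measured
by Doppler echocardiography ignores pressure recovery downstream of the vena
contracta and can substantially overstate the hemodynamic burden, especially
in small pediatric outflow tracts. `votsim` implements a deliberately simple,
fully transparent in-silico model that relates the *size* of the obstruction
to the gradient and the CO in a closed-loop circulation of a reference
2-year-old child, so the two gradients (recovered vs Doppler) and the CO can
be compared across the whole severity range.

## The obstruction model

The outflow tract is treated as a circular conduit of diameter $D$ and area
$A = \pi (D/2)^2$, locally narrowed to a minimum free area
$A_{free} = r \cdot A$, with $r \in (0, 1]$ the narrowing ratio. The lesion
has negligible length: all loss is concentrated at the orifice, where the jet
contracts and then re-expands with distal vortices that dissipate mechanical
energy. The irreversible (post-recovery) gradient between the ventricle and
the section distal to the obstruction is quadratic in the flow rate $Q$:

$$\Delta p_{obs} = K_{obs}\, Q^2, \qquad
K_{obs} = f_{shape}\, \frac{\rho}{2}
\left( \frac{1}{A_{free}} - \frac{1}{A} \right)^2,$$

with $\rho$ the blood density (1060 kg/m³ by default; the value is not
critical and is configurable) and $f_{shape} \ge 1$ a morphology factor equal
to 1 for an ideal round, annular, concentric orifice. Friction along the
lesion is neglected — the loss is separation-driven. The gradient a Doppler
exam reports is instead the pre-recovery, simplified-Bernoulli estimate at
the vena contracta,

$$\Delta p_{Doppler} = 4\, V_{A_{free}}^2, \qquad
V_{A_{free}} = Q / A_{free} \ \text{(m/s)},$$

which algebraically dominates $\Delta p_{obs}$ whenever $f_{shape} = 1$
(because $1/A_{free}^2 > (1/A_{free} - 1/A)^2$); the gap between the two is
the pressure-recovery effect.

Internally the package works in clinical units — mmHg, mL, s — and the two
SI conversions (loss coefficient, jet velocity) are localized in
`compute_K_obs()` and `doppler_dp()`. A unit-consistency test evaluates the
whole chain in SI and checks agreement to $10^{-10}$ relative.

## The closed-loop circulation

The circulation is lumped into 8 volume states: four heart chambers (LA, LV,
RA, RV) and four vascular compartments (systemic arterial and venous,
pulmonary arterial and venous). Chambers follow the time-varying elastance
law $p = E(t)(V - V_0)$; vascular compartments are linear capacitors
$p = (V - V_0)/C$ with a resistive outflow (the arterial compartments' $R$ is
the microvascular bed, the venous compartments' $R$ the venous return). The
four valves are resistive on/off diodes, $Q = \max(\Delta p, 0)/R_v$, with
semilunar resistances small enough that the mean trans-valvular drop stays
around 1–2 mmHg and never confounds the obstruction gradient. The obstruction
is inserted in series with the aortic (LVOT) or pulmonary (RVOT) valve; the
branch flow then solves $K_{obs} Q^2 + R_v Q = \Delta p$ in closed form,
which is possible precisely because the branch carries no inertance. Each
compartment's $\dot V$ is inflow minus outflow, so the derivatives sum to
zero identically and total blood volume is conserved to integrator accuracy
(checked to $10^{-6}$ relative on every run).

### Elastance activation and the role of `rise_frac`

$E(t)$ cycles between $E_{min}$ and $E_{max}$ through a normalized,
continuously differentiable raised-cosine bump of duration
$\tau_{sys} \cdot T$ (all timing is expressed in cycle fractions so the same
chamber works at any heart rate; atrial activation is placed late in the
cycle so atrial contraction immediately precedes ventricular systole). The
bump is asymmetric: a fraction `rise_frac` of it is spent contracting
(reaching $E_{max}$) and the rest relaxing. This asymmetry is not cosmetic.
With purely resistive valves and no blood inertia, forward flow stops the
moment ventricular pressure falls below arterial pressure, which happens
almost immediately once $E(t)$ starts to fall — ejection is confined to the
rising limb of the elastance. A symmetric bump therefore produces an
unphysiologically short, spiky ejection (about 0.1 s with a flow peak well
above 300 mL/s at this heart rate). Setting `rise_frac` ≈ 0.9 for the
ventricles slows the pressure build-up, which restores the physiological
ejection period (about 0.2 s at 105 bpm) and the reference peak aortic flow
(about 200 mL/s) while keeping the activation C¹ for the stiff solver. (In
models *with* inertance the same waveform emerges from blood momentum; here
the activation shape has to carry that role.)

## Parameterization and calibration

The model's compartment values for the reference 2-year-old (heart rate 105
bpm, BSA 0.55 m², body mass 12 kg, LVOT/RVOT diameters 0.9/1.07 cm) are not
taken from a published table; they were produced once by the repository
script `scripts/calibrate.R` and frozen into
`inst/extdata/child-2yr.yaml` — the package never re-calibrates at runtime.
The script starts from physiologically motivated pediatric values and runs a
weighted Nelder–Mead least-squares fit of the *baseline* (unobstructed)
simulation against reference hemodynamics of a healthy child of that age: CO
2.2 L/min, systolic/diastolic systemic pressure 93/64 mmHg, mean arterial
pressure ≈72 mmHg, peak aortic flow 200 mL/s, LV 94/3 mmHg, RV 18/2 mmHg,
pulmonary artery 17/9 mmHg, mean left/right atrial pressure 5.7/3.6 mmHg,
with the mean aortic-valve drop constrained below 2 mmHg. One reference
inconsistency is worth recording: a systemic vascular resistance of 2.0
mmHg·s/mL cannot hold exactly together with MAP ≈ 70 mmHg, CO 2.2 L/min and
right atrial pressure 3.9 mmHg under the definition used here,
$SVR = (MAP - \bar p_{RA})/CO$; the calibration targets are therefore chosen
mutually consistent (MAP 74, $p_{RA}$ 3.5, SVR ≈ 1.94), keeping every
quantity within 10% of its reference value.

The pressure and flow targets pin each ventricle's $(E_{min}, E_{max})$ pair
only *jointly*: a much more compliant ventricle (both values scaled down)
reproduces the same baseline pressures while dilating almost without bound
under afterload, which would make the obstructed regime — where the
ventricle must generate the extra gradient — essentially arbitrary. That
degeneracy is resolved with an independent piece of physiology: standard
pediatric end-diastolic volumes for a BSA of 0.55 m² (about 32 mL left, 35
mL right, giving ejection fractions near 60%) enter the fit as soft targets.
Obstructed runs are *never* part of the calibration: every sweep result is
an emergent prediction of the frozen baseline set.

A second profile, `child-10yr` (heart rate 75 bpm, BSA 1.10 m²), is derived
from the frozen set by allometric BSA scaling (volumes and compliances scale
with BSA, resistances and elastances inversely, with a slightly steeper drop
in systemic microvascular resistance). It ships as an experimental
comparison profile: no equivalent reference table constrains it.

## Numerics

* **Integrator** — `deSolve::lsoda` (adaptive, switches to a stiff BDF
  method as needed), relative tolerance $10^{-6}$, absolute $10^{-8}$ mL.
  Any implicit adaptive stiff method satisfying the refinement-invariance
  property (CO changes by $<10^{-4}$ relative when tolerances are halved —
  tested) would do.
* **Periodic steady state** — the system is integrated beat by beat from a
  fixed initial distribution of the total blood volume (unstressed volumes
  filled first, the stressed remainder split in fixed physiological
  proportions, venous pooling dominating). Convergence is declared when
  every compartment's beat-start volume changes by less than $10^{-3}$
  relative between consecutive beats (the criterion is exposed in
  `solver_options()`); the steady state is independent of the
  initialization, which is property-tested, so warm-starting sweep points
  from the previous ratio's converged state is purely a speed optimization.
* **Output sampling** — the converged beat is sampled at 2000 points;
  gradient peaks are sharp at severe narrowing, and doubling the sampling
  changes CO and mean gradients by $<10^{-4}$ relative (tested).
* **Ejection window** — the maximal contiguous interval with outflow above
  $10^{-9}$ mL/s, detected circularly so a window wrapping the beat boundary
  is handled; no ejection at all (circulatory collapse) and multiple
  distinct windows are reported as errors, never silently zeroed. One
  genuine model regime deserves note: under a very severe obstruction the
  distal arterial pressure collapses below the ventricular diastolic
  pressure and the diode never closes — a trickle flows all cycle, and the
  single contiguous window is then the whole period. Because the
  ejection-average is taken over that longer window, the *mean* gradient is
  no longer monotone in the narrowing ratio in this extreme tail (below
  $r \approx 0.1$ on the right side); monotonicity holds, and is tested,
  wherever the valve still closes.
* **Threshold crossings** — severity landmarks (e.g. the narrowing ratio
  where the mean gradient reaches 20 mmHg) are located by monotone
  piecewise-linear interpolation on the sweep grid (step 0.025); a gradient
  "reaches" the 30–35 mmHg moderate/severe band when it crosses the band's
  lower edge (30 mmHg) as severity increases.
* **Degenerate inputs** — `narrowing_ratio` outside (0, 1] and
  non-physical parameters are rejected at construction; $r \to 0$ drives
  $K_{obs} \to \infty$ and is excluded below 0.05 in sweeps because the
  circulation collapses to near-zero CO.

## What the experiments show

`narrowing_sweep()` reproduces the clinically recognized asymmetry between
the two sides: at equal narrowing ratio the LVOT gradient is larger (the
smaller conduit and the stiffer left ventricle), while RVOT obstruction
depresses CO more at its critical gradient because the right ventricle
cannot sustain comparable pressure overload. The Doppler/recovered
comparison shows the pressure-recovery effect concentrated on the left side:
the Doppler gradient crosses the moderate/severe band at roughly twice the
narrowing ratio of the recovered gradient for LVOT obstruction, while for
RVOT both gradients stay low until much smaller ratios. `fshape_sensitivity()`
propagates morphology uncertainty ($f_{shape} > 1$ inflates $K_{obs}$
linearly and shifts fixed-gradient crossings to milder ratios), and
`parameter_sensitivity_oat()` gives one-at-a-time relative sensitivities of
CO, SBP and the mean gradient to every scalar parameter (a deliberate,
transparent substitute for a variance-based global analysis, which is out of
scope).

## Limitations

The model inherits the simplifications it is built on: a concentric circular
orifice (real lesions are irregular and outflow tracts are slightly
elliptical — `f_shape` only partially absorbs this); no ventricular
adaptation or remodelling, so severe chronic obstruction is reproduced
*without* the compensatory mechanisms a real ventricle would recruit; no
baroreflex; resistive valves without inertance, so flow waveform shape is
controlled by the activation function rather than by blood momentum; and a
single reference subject per profile. The synthetic severity sweeps are
therefore trend-level predictions — the validated surface is the baseline
hemodynamics plus the clinically reported landmark ratios, not patient-level
waveforms.

## Problem sizes

The shipped configuration converges the baseline in a few seconds; a full
severity sweep (39 ratios, warm-started from the previous ratio's converged
state) takes tens of seconds per side at the default tolerances. The test
suite uses coarser ratio grids for the property checks and the full default
grid only in the acceptance tests.
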