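---
title: "Subject-specific circulation models from minimal measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subject-specific circulation models from minimal measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvsid)
```

## The model

`cvsid` simulates a six-chamber lumped-parameter model of the
cardiovascular system: left and right ventricles, aorta, vena cava,
pulmonary artery and pulmonary vein, connected in a closed loop through
four pressure-gated valves (mitral, aortic, tricuspid, pulmonary) and
the systemic and pulmonary vascular resistances.  The state is the six
chamber volumes; all flows are resistive (valve inertances are zero in
this formulation), so each valve is an ideal diode whose flow is the
forward pressure drop over its resistance, clamped at zero.

The ventricles are actively elastic.  A normalised driver function
`e(t)` in [0, 1] (the time-varying elastance) blends the linear
end-systolic relation and the exponential end-diastolic relation of each
free wall:

    P_fw(V, t) = e(t) E_es (V - V_d) + (1 - e(t)) P_0 (exp(lambda (V - V_0)) - 1)

The default driver is a normalised Gaussian pulse peaking at 30% of the
beat.  Its width is fixed in *normalised* time, `W = 45 / T^2`
(equivalently `W = 80 1/s^2` at a period of 0.75 s): systole must occupy
a roughly constant fraction of the beat across the 80-160 bpm range the
package targets, and a width fixed in absolute time would leave the
driver substantially activated at the beat boundary at high heart
rates, placing the atrioventricular closure before the start of the
beat.

Ventricular interaction enters twice.  The septum is a third active
wall whose deflection volume solves the free-wall pressure balance
`P_spt(V_spt) = P_lvf(V_lv - V_spt) - P_rvf(V_rv + V_spt)`; the residual
is strictly monotone, so the root is unique (solved by safeguarded
Newton to 1e-6 mL).  The pericardium adds
`P_pcd = P_0pcd (exp(lambda_pcd (V_lv + V_rv - V_0pcd)) - 1)` to both
ventricular pressures.  All constants take the standard published
values (`cvs_constants()`); the ventricular dead-space volumes are
23 mL.

### Numerics

The right-hand side, the septum root solve and the integrator live in
compiled code.  Integration uses an adaptive Dormand-Prince 5(4) scheme
at `rtol = atol = 1e-7` with dense sampling on the output grid (200 Hz
by default).  With inertances at zero the system's shortest time
constants are of order `R/E` approx 10-30 ms, so a stiff implicit method is
unnecessary; the explicit adaptive scheme resolves the non-smooth diode
switchings through its own step control.  Two checks in the test suite
justify this choice: the sampled aortic pressure changes by under
0.1 mmHg when the tolerances are halved, and a one-beat closed-loop
integration agrees with an independent `deSolve::lsoda` solution of the
R-level derivatives.  Closed-loop volume is conserved to better than
1e-3 mL over 20 beats.

The periodic steady state is found by integrating beat to beat until
the chamber volumes at beat onset move by less than 0.01 mL (at most
300 beats; reaching the cap flags, rather than raises, non-convergence).
The slowest closed-loop mode is the venous redistribution time constant
(a few seconds), so convergence typically takes 15-60 beats.

## Feature extraction

A beat-level record is reduced to the convergence set points that drive
identification: global end diastolic volume (GEDV, the sum of the two
ventricular maxima), stroke volume (SV, the average of the two
ventricular volume amplitudes), mean/pulse/maximum-ascending-gradient of
the aortic and pulmonary artery pressures, the mitral and tricuspid
closure times, and the period.

Two conventions matter:

* **Smoothing.**  Each measured trace is smoothed with a cubic
  Savitzky-Golay filter before features are read off (window of 7
  samples at the 200 Hz reference rate, rescaled in proportion to the
  actual sampling rate so the filtered bandwidth is rate independent).
  The identification applies the *same* smoothing to the model-side
  beats, so the filter's small peak-flattening bias cancels exactly
  between measurement and model.  The window is a compromise: large
  enough to keep max/min read-offs useful under multiplicative
  measurement noise, small enough that the noiseless round trip from
  simulator to set points stays within half a percent.
* **Closure times.**  When inflow-flow traces are present (synthetic
  records carry them), closure is the cessation of mitral/tricuspid
  flow, with the crossing interpolated on the valve's gating pressure
  difference -- interpolating the clamped flow itself would quantise the
  instant to the sample grid.  For records without flows, a driver
  function is first estimated from the arterial pressure shape
  (`estimate_driver()`), and closure is read off as the time the
  activation crosses 5% of its maximum.

## The staged identification

Each observable drives exactly one parameter through the multiplicative
update `P <- P * (measurement / output)` (or its inverse for inversely
related pairs).  Update directions are resolved at run time from the
sign of a +5% sensitivity simulation (`relation_direction()`), with a
physiological lookup table as fallback.

Stage one identifies the decoupled systemic submodel (fixed
pulmonary-vein source pressure): GEDV/2 drives `E_es_lvf`, SV drives
`R_mt`, MAP drives `R_sys`, aortic pulse pressure drives `E_ao`, the
maximum aortic gradient drives `R_av`, and the mitral closure time
drives the source pressure `P_pu`.  Stage two mirrors this for the
pulmonary side.  Stage three joins the submodels through septal and
pericardial coupling and re-applies every pairing on the coupled model
until all matched outputs reproduce their measurements.

Three aspects of the coupled stage deserve explanation.

**Closure phases.**  Valve closure happens within milliseconds of beat
onset, so the raw closure time of two similar models can fall on either
side of the beat boundary; ratios of such numbers are meaningless.
Identification therefore matches the closure *phase* relative to the
driver peak, `(t_close - t_peak) mod T`, which is continuous across the
wrap and of order half a period.  Phases carry a looser tolerance than
the other outputs (5% by default): a few percent of phase corresponds
to a fraction of a millimetre of mercury of venous pressure, which is
all the information the closure instant carries.

**The left/right volume split.**  GEDV constrains only the *sum* of the
end diastolic volumes.  Along the direction that trades left against
right volume -- with the two ventricular elastances compensating -- the
measurement set is almost blind: maximum ventricular pressures are
pinned by the (matched) arterial pressures, and the closure phases are
absorbed by the venous side.  The method therefore treats volume
balance as a modelling assumption: the coupled stage drives the sum
through symmetric updates of both elastances, plus weak per-ventricle
updates centring the split on GEDV/2 (these act only along the blind
direction and are excluded from the convergence check).  The virtual
subjects are generated balanced (see below), which is also what the
porcine cohort shows: the measured median end diastolic volumes differ
by under five percent.

**The venous side.**  At periodic steady state the mean pulmonary-vein
pressure obeys the identity `P_pu = MPAP - CO * R_pul`, and both MPAP
and cardiac output are measured.  Once they are matched, the venous
elastance has essentially no authority over the venous pressure level;
only the within-beat swing responds, weakly.  Venous quantities are
consequently weakly identifiable from this measurement set -- the central
numerical difficulty of the whole problem.  The package handles it by
nesting: the joint proportional-gain loop runs with the venous
elastances frozen, and an outer secant adjusts `E_pu` and `E_vc`
against the two closure-phase residuals, accepting a step only when the
phases improve and keeping the best visited state.  Total stressed
volume and the venous compliance scale are held at population constants
(280 mL, 0.12 mmHg/mL): neither is observable from the set points (any
total volume can be compensated by the other parameters), and the
residual venous-level uncertainty is the dominant error source for
`R_pul` (mean pressure drop `MPAP - P_pu` is only ~10 mmHg, so half a
millimetre of venous pressure error is five percent of `R_pul`).

Convergence is two-tier: the inner tolerance (0.1%) terminates the
update iteration, and a model is flagged converged when every matched
measurement output agrees within 0.5% -- the whole-model bound the
method is designed to deliver -- and the phases within their own
tolerance.  Non-convergence is a reported state, never an exception, so
a nine-timepoint series survives an ill-behaved timepoint.

For a subject's series of timepoints the four valve resistances are
averaged over the converged timepoints and everything else is
re-identified per timepoint with the valves fixed (`identify_subject()`).

## The virtual-subject generator

Because no catheter data ship with the package, a generator produces
ground-truth subjects end to end.  A baseline draws the ten
staged-identification parameters uniformly within +/-30% of the standard
initial tables and the heart rate in 80-160 bpm, then solves the right
ventricular elastance (bisection within its +/-30% band) so the two end
diastolic volumes balance, and accepts the draw only if the steady
state passes a physiological screen (MAP 50-130 mmHg, SV 20-60 mL).
Septic shock is imposed as phenomenological multiplicative trends,
logistic in time between the 30 and 120 minute timepoints: systemic
resistance falls by 42% at T120, pulmonary resistance rises by 50%,
heart rate rises by 10%, contractilities stay constant; responders
recover a configurable fraction of the systemic drop after the trough.
Nine timepoints at 30-minute spacing emulate the T0...T240 protocol.

Measurement noise is multiplicative Gaussian per sample (3% SD by
default) applied to the six catheter-measured signals only; the flow
traces and venous pressures carried in the synthetic records are model
outputs, not measurements, and stay clean.  An optional amplitude
factor on the right ventricular volume emulates the conductance
catheter's systematic underestimation of right ventricular volume.

What the generator does *not* emulate: baroreflex and autonomic
control, respiratory intrathoracic pressure variation, beat-to-beat
variability, catheter drift or baseline wander, and band-limited
(coloured) noise.  Passing tests on this cohort therefore demonstrate
the method's internal consistency and noise robustness, not its
accuracy on animals.

## Problem sizes and tunables

The test suite and the acceptance script use cohorts of 20 virtual
subjects for the single-timepoint checks and 2 subjects x 9 timepoints
for trend tracking, at 200 Hz sampling and 8 recorded beats -- sizes at
which one identification takes a few seconds.  The tunables that matter,
with defaults:

| parameter | default | meaning |
|---|---|---|
| `inner_tol` | 1e-3 | update-loop stopping tolerance per output |
| `outer_tol` | 5e-3 | whole-model convergence flag (every output) |
| `phase_tol` | 0.05 | closure-phase tolerance |
| `dead_space_V_d` | 23 mL | ventricular ESPVR intercept, held fixed |
| `smooth_window` | 7 | SG window (samples at 200 Hz) |
| `delta` | 0.05 | driver threshold defining valve closure |
| `venous_elastance` | 0.12 | population venous elastance, mmHg/mL |
| `total_volume` | 280 mL | population stressed volume |
| `ratio_clamp` | [0.5, 2] | per-iteration bound on any update |
| `damping` | 0.5 | step shrink on residual growth |

## Known limitations

* The left/right volume split and the venous pressure levels are weakly
  identifiable from this measurement set; the method resolves them with
  the balanced-volume assumption and population venous constants.  On
  subjects whose closure phases respond weakly, `R_pul` and `E_pa` can
  carry residual errors of order ten percent even noiselessly.
* Valve-closure information is used through a reconstruction of the
  driver-estimation method (the original algorithm is not reproduced in
  the source literature); the parametric fallback keeps the pipeline
  total.
* Identification assumes steady-state beats; arrhythmic or unstable
  records should be screened out upstream.
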