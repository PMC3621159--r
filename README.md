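# cvsid

Subject-specific lumped-parameter cardiovascular models from minimal
hemodynamic measurements.

## What this is for

In intensive care, the quantities clinicians most want — ventricular
preload (end diastolic volumes), afterload (systemic and pulmonary
vascular resistance) and contractility (end-systolic elastance) — are
difficult or impossible to measure continuously.  `cvsid` implements a
model-based monitoring approach: a six-chamber lumped-parameter model
of the heart and circulation is fitted to a *minimal*, clinically
available measurement set, and the fitted model's internal state then
serves as a continuous estimate of those hidden quantities.

The measurement set per timepoint is the set of "convergence set
points":

| symbol | measurement |
|---|---|
| GEDV | global end diastolic volume (LVEDV + RVEDV) |
| SV | stroke volume |
| MAP, MPAP | mean aortic / pulmonary artery pressure |
| PP_ao, PP_pa | aortic / pulmonary artery pulse pressure |
| dP_ao,max/dt, dP_pa,max/dt | maximum ascending pressure gradients |
| t_mt, t_tc | mitral / tricuspid valve closure times |
| T | heartbeat period |

## The model and the method

The circulation is six elastic chambers in a closed loop.  Ventricular
free walls are actively elastic with a normalised time-varying
elastance `e(t)`:

    P_fw = e(t) E_es (V - V_d) + (1 - e(t)) P_0 (exp(lambda (V - V_0)) - 1)

the passive chambers are linear (`P = E (V - V_d)`), the four heart
valves are pressure-gated ideal diodes, and the ventricles interact
through a septal wall (its deflection solves an implicit pressure
balance) and a common pericardium.  Simulation is compiled
(Rcpp/Dormand-Prince) and samples pressures, volumes and flows at
200 Hz.

Identification is an iterative proportional-gain scheme: each
observable output is paired with one parameter, which is updated
multiplicatively by `P <- P (measurement / output)` (or the inverse
ratio for inversely related pairs) around repeated steady-state
simulations.  The systemic and pulmonary submodels are identified
first in decoupled form, then joined through the septum and
pericardium and re-identified in the coupled context; over a subject's
series of timepoints the valve resistances are averaged and everything
else re-identified with valves fixed.  Derived afterload indices
`E_a = (R_pv + R_pul)/T` and right ventricular-arterial coupling
`E_es,rvf / E_a` come with the fit.

Because no catheter recordings ship with the package, a virtual-subject
generator produces ground-truth cohorts: baselines drawn around the
standard initial parameter tables, a phenomenological septic-shock
trajectory (systemic resistance falling 42% by two hours, pulmonary
resistance rising, mild tachycardia) over nine timepoints at 30-minute
spacing, and multiplicative measurement noise.  Bland–Altman bias and
precision, R², and absolute-percentage-error summaries validate the
identified models against the generating truth.

See the methods vignette (`vignettes/cvsid-methods.Rmd`) for the model
equations, the numerical choices, and an honest discussion of what is
and is not identifiable from this measurement set.

## Worked example

```r
library(cvsid)

# a virtual subject and one noiseless timepoint
subject <- sample_baseline(seed = 3)
ds <- generate_dataset(subject, sepsis_config(n_timepoints = 1,
                                              noise_sd = 0), seed = 3)
ds$setpoints$T0[, c("GEDV", "SV", "MAP", "MPAP", "PP_ao")]
#> # A tibble: 1 x 5
#>    GEDV    SV   MAP  MPAP PP_ao
#>   <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1  187.  22.6  89.0  17.2  40.7

fit <- identify_model(ds$setpoints$T0)
glance(fit)[, c("converged", "worst_residual_pct", "LVEDV", "RVEDV")]
#> # A tibble: 1 x 4
#>   converged worst_residual_pct LVEDV RVEDV
#>   <lgl>                  <dbl> <dbl> <dbl>
#> 1 TRUE                   0.443  93.4  93.4

tidy(fit)[tidy(fit)$term %in% c("E_es_lvf", "R_sys", "E_ao"), ]
#> # A tibble: 3 x 2
#>   term     estimate
#>   <chr>       <dbl>
#> 1 E_es_lvf     2.52
#> 2 R_sys        2.40
#> 3 E_ao         2.15

# how close is that to the generating truth?
unlist(ds$truth$T0$params[c("E_es_lvf", "R_sys", "E_ao")])
#> E_es_lvf    R_sys     E_ao
#> 2.505310 2.403358 2.151104
```

The identified model reproduces its five matched measurements (MAP,
MPAP, both pulse pressures, stroke volume) to a fraction of a percent —
the operational definition of convergence — and recovers the generating
resistances and elastances to a few percent; the `worst_residual_pct`
column includes the loosely constrained valve-closure phases.

`autoplot()` methods plot simulated waveform sets and identified
parameter trajectories; `plot_bland_altman()` draws the agreement
analysis.

A thin command-line interface covers the pipeline
(`inst/scripts/cvsid`): `simulate`, `features`, `identify`,
`identify-series`, `synth`, `validate`.

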