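#' Identification configuration
#'
#' Collects the tunables of the staged proportional-gain identification:
#' convergence tolerances, iteration caps, the fixed ventricular
#' dead-space volume, the update relaxation and damping, and the feature
#' extraction settings shared between the measured and modelled sides.
#'
#' @param inner_tol Relative tolerance on every matched output within a
#'   stage (default 1e-3, i.e. 0.1 percent).
#' @param outer_tol Whole-model convergence tolerance: an identified
#'   model is flagged converged when every matched measurement output
#'   agrees with its measurement to within this relative tolerance
#'   (default 0.5 percent) and the closure phases within `phase_tol`.
#' @param max_inner,max_outer Iteration caps for the submodel stages and
#'   the coupled stage.
#' @param dead_space_V_d Ventricular ESPVR dead-space volume held fixed
#'   during identification, mL.
#' @param relations `"auto"` to resolve each update direction at run time
#'   from the sign of a +5 percent sensitivity simulation, or `"builtin"`
#'   for the precomputed physiological table; a named character vector of
#'   `"proportional"`/`"inverse"` entries overrides individual pairs.
#' @param relax Exponent applied to each multiplicative update (1 = full
#'   proportional step).
#' @param damping Extra relaxation factor applied when an iteration
#'   overshoots (the worst residual grows).
#' @param ratio_clamp Two-sided clamp on any single multiplicative update.
#' @param smooth_window Savitzky-Golay window used for all feature
#'   extraction (measured and modelled side alike).
#' @param delta Driver threshold defining valve closure.
#' @param f_s Sampling frequency of model beats during identification.
#' @param venous_elastance Nominal venous elastance (mmHg/mL) used to
#'   size the vena cava and pulmonary vein pools when the submodels are
#'   joined (venous compliance is not observable from the set points).
#' @param total_volume Total stressed blood volume in mL, held at the
#'   population constant during identification (not observable from the
#'   set points).
#' @param phase_tol Relative tolerance on the valve closure phases,
#'   looser than the output tolerances: a few percent of phase
#'   corresponds to a fraction of a millimetre of mercury in venous
#'   pressure, beneath the resolution the closure times carry.
#' @param fix_valves If `TRUE` the four valve resistances are held at
#'   their current values (used in the re-identification pass of a
#'   subject series).
#' @param verbose If `TRUE`, log the per-iteration worst residual of each
#'   stage via `message()`.
#' @return A list of class `cvs_ident_config`.
#' @export
identification_config <- function(inner_tol = 1e-3, outer_tol = 5e-3,
                                  max_inner = 200, max_outer = 20,
                                  dead_space_V_d = 23,
                                  relations = "auto", relax = 1,
                                  damping = 0.5, ratio_clamp = c(0.5, 2),
                                  smooth_window = 7, delta = 0.05,
                                  f_s = 200, venous_elastance = 0.12,
                                  total_volume = 280, phase_tol = 0.05,
                                  fix_valves = FALSE, verbose = FALSE) {
  stopifnot(inner_tol > 0, inner_tol < 1, outer_tol > 0, outer_tol < 1,
            max_inner >= 1, max_outer >= 1)
  structure(list(inner_tol = inner_tol, outer_tol = outer_tol,
                 max_inner = max_inner, max_outer = max_outer,
                 dead_space_V_d = dead_space_V_d, relations = relations,
                 relax = relax, damping = damping,
                 ratio_clamp = ratio_clamp, smooth_window = smooth_window,
                 delta = delta, f_s = f_s,
                 venous_elastance = venous_elastance,
                 total_volume = total_volume, phase_tol = phase_tol,
                 fix_valves = fix_valves, verbose = verbose,
                 relation_cache = new.env(parent = emptyenv())),
            class = "cvs_ident_config")
}

#' Proportional-gain parameter update
#'
#' One multiplicative update of a parameter towards matching its paired
#' model output: parameters proportional to their output are scaled by
#' `measurement / model_output`; inversely related parameters by
#' `model_output / measurement`.  At `measurement == model_output` the
#' update is the identity (fixed point).
#'
#' @param p_old Current parameter value (> 0).
#' @param measurement Measured set-point value (> 0).
#' @param model_output Corresponding model output (> 0, same units).
#' @param relation `"proportional"` or `"inverse"`.
#' @return Updated parameter value (> 0).
#' @export
#' @examples
#' proportional_update(2, measurement = 90, model_output = 60)       # 3
#' proportional_update(2, 60, 90, relation = "inverse")              # 3
proportional_update <- function(p_old, measurement, model_output,
                                relation = c("proportional", "inverse")) {
  relation <- match.arg(relation)
  if (!all(p_old > 0, measurement > 0, model_output > 0) ||
      !all(is.finite(c(p_old, measurement, model_output))))
    stop("invalid update: inputs must be positive and finite")
  r <- if (relation == "proportional") measurement / model_output
       else model_output / measurement
  p_old * r
}

# ---- model-output extraction (shared measured/modelled conventions) ----

stage_output_names <- function(stage) {
  switch(stage,
    systemic = c("LVEDV", "SV_lv", "MAP", "PP_ao", "dPao_max", "t_mt"),
    pulmonary = c("RVEDV", "SV_rv", "MPAP", "PP_pa", "dPpa_max", "t_tc"),
    closed = c("GEDV", "SV_lv", "SV_rv", "MAP", "MPAP", "PP_ao", "PP_pa",
               "dPao_max", "dPpa_max", "t_mt", "t_tc", "P_vc_mean",
               "P_pu_mean"))
}

model_outputs <- function(w, stage, cfg) {
  f_s <- attr(w, "f_s")
  sm <- function(x) smooth_trace(x, cfg$smooth_window, f_s)
  t <- w$t - w$t[1]
  out <- list()
  if (stage %in% c("systemic", "closed")) {
    V_lv <- sm(w$V_lv); P_ao <- sm(w$P_ao)
    out$LVEDV <- end_diastolic_volume(V_lv)
    out$SV_lv <- waveform_amplitude(V_lv)
    out$MAP <- waveform_mean(P_ao)
    out$PP_ao <- waveform_amplitude(P_ao)
    out$dPao_max <- max_ascending_gradient(P_ao, f_s)
    # closure interpolated on the same smoothed gating pressure the
    # measured-side extractor uses, so the smoothing bias cancels
    out$t_mt <- closure_time_from_flow(w$Q_mt, t, w$P_pu - sm(w$P_lv))
  }
  if (stage %in% c("pulmonary", "closed")) {
    V_rv <- sm(w$V_rv); P_pa <- sm(w$P_pa)
    out$RVEDV <- end_diastolic_volume(V_rv)
    out$SV_rv <- waveform_amplitude(V_rv)
    out$MPAP <- waveform_mean(P_pa)
    out$PP_pa <- waveform_amplitude(P_pa)
    out$dPpa_max <- max_ascending_gradient(P_pa, f_s)
    out$t_tc <- closure_time_from_flow(w$Q_tc, t, w$P_vc - sm(w$P_rv))
  }
  if (stage == "closed") {
    out$GEDV <- out$LVEDV + out$RVEDV
    out$P_vc_mean <- waveform_mean(w$P_vc)
    out$P_pu_mean <- waveform_mean(w$P_pu)
    # venous pressures at the instant the inflow valve closes: these are
    # the quantities the decoupled stages estimate from the measured
    # closure times (a fixed-source submodel sees the venous pressure at
    # closure, not the beat mean)
    out$P_pu_close <- if (is.na(out$t_mt)) NA_real_
      else approx(t, w$P_pu, xout = out$t_mt, rule = 2)$y
    out$P_vc_close <- if (is.na(out$t_tc)) NA_real_
      else approx(t, w$P_vc, xout = out$t_tc, rule = 2)$y
    out$P_lv_max <- max(w$P_lv)
    out$P_rv_max <- max(w$P_rv)
  }
  out
}

# Valve closure sits within a few milliseconds of beat onset, so the raw
# closure time can fall on either side of the beat boundary between two
# otherwise similar models.  Identification therefore matches the
# closure *phase* relative to the driver peak, ((t_close - t_peak) mod T),
# which is continuous across the wrap and O(half a period) in size.
closure_phase <- function(t_close, t_peak, period) {
  (t_close - t_peak) %% period
}

builtin_relations <- c(
  "E_es_lvf:LVEDV" = "inverse",   "E_es_lvf:GEDV" = "inverse",
  "R_mt:SV_lv" = "inverse",       "R_sys:MAP" = "proportional",
  "E_ao:PP_ao" = "proportional",  "R_av:dPao_max" = "inverse",
  "P_pu:t_mt" = "proportional",   "P_pu:phi_mt" = "proportional",
  "P_vc:phi_tc" = "proportional",
  "P_pu_target:phi_mt" = "proportional",
  "P_vc_target:phi_tc" = "proportional",
  "E_es_rvf:RVEDV" = "inverse",   "E_es_rvf:GEDV" = "inverse",
  "R_tc:SV_rv" = "inverse",       "R_pul:MPAP" = "proportional",
  "E_pa:PP_pa" = "proportional",  "R_pv:dPpa_max" = "inverse",
  "P_vc:t_tc" = "proportional",
  "E_vc:P_vc_mean" = "proportional", "E_pu:P_pu_mean" = "proportional",
  "R_pul:phi_mt" = "inverse",        "E_pu:MPAP" = "proportional",
  "E_pu:P_pu_close" = "proportional", "E_vc:P_vc_close" = "proportional",
  "E_pu:phi_mt" = "proportional",    "E_vc:phi_tc" = "proportional",
  "V_total:phi_mt" = "proportional",  "V_total:phi_tc" = "proportional")

#' Direction of a parameter/output pairing
#'
#' Decides whether a model output responds proportionally or inversely to
#' its paired parameter by perturbing the parameter +5 percent,
#' re-simulating to steady state, and reading the sign of the output
#' change.  Results are cached per configuration.
#'
#' @param parameter_name Parameter symbol (e.g. `"R_sys"`).
#' @param output_name Model output symbol (e.g. `"MAP"`).
#' @param params A `cvs_params` object at which to linearise.
#' @param stage `"systemic"`, `"pulmonary"`, or `"closed"`.
#' @param cfg An [identification_config()].
#' @return `"proportional"` or `"inverse"`.
#' @export
relation_direction <- function(parameter_name, output_name, params,
                               stage = "closed",
                               cfg = identification_config()) {
  key <- paste(parameter_name, output_name, stage, sep = ":")
  cache <- cfg$relation_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  base <- steady_state_beat(params, f_s = cfg$f_s, mode = stage)
  out0 <- model_outputs(base, stage, cfg)[[output_name]]
  if (is.null(out0))
    stop("output ", output_name, " is not a simulated quantity")
  pert <- params
  pert[[parameter_name]] <- pert[[parameter_name]] * 1.05
  wp <- steady_state_beat(pert, f_s = cfg$f_s, mode = stage,
                          init = attr(base, "final_state"))
  out1 <- model_outputs(wp, stage, cfg)[[output_name]]
  if (any(is.na(c(out0, out1))) ||
      abs(out1 - out0) < 1e-6 * max(abs(out0), 1e-12))
    stop("output ", output_name, " is insensitive to ", parameter_name)
  rel <- if (out1 > out0) "proportional" else "inverse"
  cache[[key]] <- rel
  rel
}

resolve_relation <- function(param, output, params, stage, cfg) {
  key <- paste0(param, ":", output)
  if (is.character(cfg$relations) && !is.null(names(cfg$relations)) &&
      key %in% names(cfg$relations))
    return(unname(cfg$relations[[key]]))
  if (identical(cfg$relations, "builtin")) {
    rel <- builtin_relations[[key]]
    if (is.null(rel)) stop("no builtin relation for ", key)
    return(rel)
  }
  lookup <- if (param %in% c("P_pu_target", "P_vc_target"))
    sub("_target", "", param) else param
  tryCatch(
    relation_direction(lookup, output, params, stage, cfg),
    error = function(e) {
      if (!key %in% names(builtin_relations)) stop(e)
      builtin_relations[[key]]
    })
}

# physiological box constraints keeping the multiplicative iteration out
# of degenerate regimes (mush ventricles, vanishing resistances)
param_bounds <- list(
  E_es_lvf = c(0.1, 20), E_es_rvf = c(0.05, 20),
  R_mt = c(5e-3, 2), R_av = c(5e-3, 2), R_tc = c(5e-3, 2),
  R_pv = c(5e-3, 2), R_sys = c(0.05, 30), R_pul = c(0.01, 15),
  E_ao = c(0.1, 30), E_pa = c(0.1, 30), E_vc = c(0.005, 5),
  E_pu = c(0.005, 5), P_pu = c(0.8, 15), P_vc = c(0.8, 15),
  V_total = c(120, 700))

clamp_param <- function(name, value) {
  b <- param_bounds[[name]]
  if (is.null(b)) return(value)
  min(max(value, b[1]), b[2])
}

# one proportional-gain pass over a set of pairings; `exponent` allows a
# shared measurement (GEDV) to split its correction over two parameters
# or to soften hypersensitive pairings (valve closure times)
apply_updates <- function(params, pairs, outs, meas, relations, relax,
                          clamp) {
  for (p in pairs) {
    out <- outs[[p$output]]
    m <- meas[[p$target]]
    if (is.null(out) || is.na(out) || is.na(m) || out <= 0 || m <= 0) next
    if (!is.null(p$skip_if) && p$skip_if(out)) next
    r <- if (relations[[paste0(p$param, ":", p$output)]] == "proportional")
      m / out else out / m
    r <- r^(relax * (p$exponent %||% 1))
    r <- min(max(r, clamp[1]), clamp[2])
    params[[p$param]] <- clamp_param(p$param, params[[p$param]] * r)
  }
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

residual_table <- function(outs, meas, pairs) {
  purrr::map_dfr(pairs, function(p) {
    out <- outs[[p$output]] %||% NA_real_
    m <- meas[[p$target]] %||% NA_real_
    tibble(output = p$output, parameter = p$param,
           measurement = m, model = out,
           residual_pct = 100 * abs(m - out) / abs(m))
  })
}

#' Identify one decoupled submodel
#'
#' Fits the six identifiable parameters of the systemic (or pulmonary)
#' circulation submodel to a convergence set-point record by iterating:
#' simulate the submodel to its periodic steady state, extract the model
#' outputs, and update each parameter from its paired output by the
#' proportional-gain rule, until every matched output agrees with its
#' measurement to within `inner_tol` (relative).  The decoupled stage
#' targets half the global end diastolic volume for its single ventricle;
#' the source pressure (`P_pu` systemic, `P_vc` pulmonary) is driven by
#' the valve closure-time mismatch.
#'
#' @param sp A `cvs_setpoints` row.
#' @param stage `"systemic"` or `"pulmonary"`.
#' @param driver Optional `cvs_driver`; defaults to the parametric driver
#'   at the set-point period.
#' @param init Named list of starting parameter values; defaults to the
#'   standard initial tables ([systemic_init()], [pulmonary_init()]).
#' @param cfg An [identification_config()].
#' @return List with elements `params` (full `cvs_params` carrying the
#'   stage estimates), `estimates` (named stage parameters), `residuals`
#'   (tibble), `converged`, `iterations`.
#' @export
identify_submodel <- function(sp, stage = c("systemic", "pulmonary"),
                              driver = NULL, init = NULL,
                              cfg = identification_config()) {
  stage <- match.arg(stage)
  validate_setpoints(sp)
  sp <- as.list(sp)
  if (is.null(driver)) driver <- cvs_driver(sp$T)
  defaults <- if (stage == "systemic") systemic_init() else pulmonary_init()
  if (!is.null(init)) defaults <- modifyList(defaults, init)
  params <- do.call(cvs_params,
                    c(defaults, list(heart_rate = 60 / sp$T, driL = driver,
                                     driR = driver)))
  params$V_d_lvf <- params$V_d_rvf <- cfg$dead_space_V_d

  pairs <- if (stage == "systemic") list(
    list(param = "E_es_lvf", output = "LVEDV", target = "half_GEDV"),
    list(param = "R_mt", output = "SV_lv", target = "SV"),
    list(param = "R_sys", output = "MAP", target = "MAP"),
    list(param = "E_ao", output = "PP_ao", target = "PP_ao"),
    list(param = "R_av", output = "dPao_max", target = "dPao_max"),
    list(param = "P_pu", output = "phi_mt", target = "phi_mt",
         exponent = 2)
  ) else list(
    list(param = "E_es_rvf", output = "RVEDV", target = "half_GEDV"),
    list(param = "R_tc", output = "SV_rv", target = "SV"),
    list(param = "R_pul", output = "MPAP", target = "MPAP"),
    list(param = "E_pa", output = "PP_pa", target = "PP_pa"),
    list(param = "R_pv", output = "dPpa_max", target = "dPpa_max"),
    list(param = "P_vc", output = "phi_tc", target = "phi_tc",
         exponent = 2)
  )
  t_peak <- driver_peak_time(driver)
  meas <- c(sp, list(half_GEDV = sp$GEDV / 2,
                     phi_mt = closure_phase(sp$t_mt, t_peak, sp$T),
                     phi_tc = closure_phase(sp$t_tc, t_peak, sp$T)))

  relations <- setNames(
    lapply(pairs, function(p)
      resolve_relation(p$param, p$output, params, stage, cfg)),
    vapply(pairs, function(p) paste0(p$param, ":", p$output), character(1)))

  warm <- NULL
  prev_worst <- Inf
  prev_params <- params
  relax_state <- cfg$relax
  stall <- 0L
  converged <- FALSE
  it <- 0
  for (it in seq_len(cfg$max_inner)) {
    w <- try(steady_state_beat(params, f_s = cfg$f_s, mode = stage,
                               init = warm), silent = TRUE)
    if (inherits(w, "try-error")) {
      # simulation failed: back off to the previous iterate, smaller step
      params <- prev_params
      warm <- NULL
      prev_worst <- Inf
      next
    }
    warm <- attr(w, "final_state")
    outs <- model_outputs(w, stage, cfg)
    if (!is.null(outs$t_mt) && !is.na(outs$t_mt))
      outs$phi_mt <- closure_phase(outs$t_mt, t_peak, sp$T)
    if (!is.null(outs$t_tc) && !is.na(outs$t_tc))
      outs$phi_tc <- closure_phase(outs$t_tc, t_peak, sp$T)
    res <- residual_table(outs, meas, pairs)
    worst <- max(res$residual_pct, na.rm = TRUE) / 100
    if (cfg$verbose)
      message(sprintf("[%s] iter %d worst residual %.4g%%", stage, it,
                      100 * worst))
    if (is.finite(worst) && worst < cfg$inner_tol) { converged <- TRUE; break }
    # stall: residual pinned (e.g. a source pressure railed at its
    # physiological bound while the phase target is unreachable in the
    # decoupled model) -- stop and let the coupled stage take over
    stall <- if (is.finite(worst) && abs(worst - prev_worst) < 1e-4)
      stall + 1L else 0L
    if (stall >= 8L) break
    # persistent damping: shrink the step while residuals grow, recover
    # slowly once they fall again
    relax_state <- if (worst > prev_worst)
      max(relax_state * cfg$damping, 0.05 * cfg$relax)
    else min(cfg$relax, relax_state * 1.1)
    prev_worst <- worst
    prev_params <- params
    params <- apply_updates(params, pairs, outs, meas, relations,
                            relax_state, cfg$ratio_clamp)
  }
  est_names <- vapply(pairs, function(p) p$param, character(1))
  list(params = params,
       estimates = setNames(lapply(est_names, function(n) params[[n]]),
                            est_names),
       residuals = res, converged = converged, iterations = it,
       stage = stage)
}

#' Join and identify the six-chamber model
#'
#' Couples the two identified submodels through the septum and
#' pericardium, then iterates the proportional-gain updates of all
#' measurement/parameter pairings in the coupled context: the global end
#' diastolic volume drives both ventricular elastances (the correction is
#' split evenly between them), stroke volume drives the inflow valve
#' resistances, the arterial features drive their respective resistances
#' and elastances, and the venous elastances `E_vc`/`E_pu` are adjusted
#' so the simulated mean vena-cava and pulmonary-vein pressures track the
#' source pressures implied by the measured valve closure times (the
#' submodel estimates serve as starting targets and are refined from the
#' closure-time residuals of the coupled model).
#'
#' @param systemic,pulmonary Results of [identify_submodel()], or `NULL`
#'   when `init` provides a full coupled starting point.
#' @param sp A `cvs_setpoints` row.
#' @param cfg An [identification_config()].
#' @param init Optional full `cvs_params` starting point (skips the
#'   submodel bootstrap).
#' @return An object of class `cvs_fit`; see [identify_model()].
#' @export
identify_sixchamber <- function(systemic, pulmonary, sp,
                                cfg = identification_config(),
                                init = NULL) {
  validate_setpoints(sp)
  spl <- as.list(sp)
  if (is.null(init)) {
    ps <- systemic$params
    pp <- pulmonary$params
    params <- ps
    for (n in c("E_es_rvf", "R_tc", "R_pv", "E_pa", "R_pul"))
      params[[n]] <- pp[[n]]
    params$P_vc <- pp$P_vc       # pulmonary-stage estimate (tricuspid timing)
    # source-pressure targets for the venous chambers; the pools are
    # sized so the nominal venous elastance reproduces those levels
    # (venous compliance itself is not observable from the set points).
    # A decoupled estimate railed at its physiological bound is known
    # to be unreliable (the fixed-source submodel could not reproduce
    # the measured closure); start from the standard initial value and
    # let the coupled-stage phase refinement find the level.
    railed <- function(x, nm) {
      b <- param_bounds[[nm]]
      x <= b[1] * 1.01 || x >= b[2] * 0.99
    }
    P_pu_target <- if (railed(ps$P_pu, "P_pu")) systemic_init()$P_pu
                   else ps$P_pu
    P_vc_target <- if (railed(pp$P_vc, "P_vc")) pulmonary_init()$P_vc
                   else pp$P_vc
    params$E_pu <- cfg$venous_elastance
    params$E_vc <- cfg$venous_elastance
    params$V_total <- cfg$total_volume
    v_pu <- P_pu_target / cfg$venous_elastance
    # warm start: submodel chamber volumes, the pulmonary-vein pool at
    # its implied size, the vena cava absorbing the remainder of the
    # fixed total stressed volume
    ws <- steady_state_beat(params, f_s = cfg$f_s, mode = "systemic")
    wp <- steady_state_beat(params, f_s = cfg$f_s, mode = "pulmonary")
    v_vc <- cfg$total_volume - (mean(ws$V_lv) + mean(ws$V_ao) +
      mean(wp$V_rv) + mean(wp$V_pa) + v_pu)
    warm <- c(mean(ws$V_lv), mean(ws$V_ao), v_vc,
              mean(wp$V_rv), mean(wp$V_pa), v_pu)
    # a railed source-pressure estimate can leave no volume for the
    # vena cava pool; fall back to the default volume split
    if (v_vc <= 5) warm <- NULL
  } else {
    params <- init
    params$V_d_lvf <- params$V_d_rvf <- cfg$dead_space_V_d
    w0 <- steady_state_beat(params, f_s = cfg$f_s, mode = "closed")
    o0 <- model_outputs(w0, "closed", cfg)
    P_pu_target <- if (is.na(o0$P_pu_close)) o0$P_pu_mean else o0$P_pu_close
    P_vc_target <- if (is.na(o0$P_vc_close)) o0$P_vc_mean else o0$P_vc_close
    warm <- attr(w0, "final_state")
  }

  # The measured GEDV constrains only the SUM of the end diastolic
  # volumes: along the direction that trades left against right volume
  # (with the elastances compensating) the measurement set is blind.
  # The symmetric pair below drives the sum; the two weak per-ventricle
  # pairs centre the split on the balanced-volume assumption that also
  # underlies the decoupled stages.  They regularise the degenerate
  # direction and are excluded from the convergence check.
  pairs <- list(
    list(param = "E_es_lvf", output = "GEDV", target = "GEDV",
         exponent = 0.5),
    list(param = "E_es_rvf", output = "GEDV", target = "GEDV",
         exponent = 0.5),
    list(param = "E_es_lvf", output = "LVEDV", target = "half_GEDV",
         exponent = 0.35, check = FALSE),
    list(param = "E_es_rvf", output = "RVEDV", target = "half_GEDV",
         exponent = 0.35, check = FALSE),
    list(param = "R_mt", output = "SV_lv", target = "SV"),
    list(param = "R_tc", output = "SV_rv", target = "SV"),
    list(param = "R_sys", output = "MAP", target = "MAP"),
    list(param = "R_pul", output = "MPAP", target = "MPAP"),
    list(param = "E_ao", output = "PP_ao", target = "PP_ao"),
    list(param = "E_pa", output = "PP_pa", target = "PP_pa"),
    list(param = "R_av", output = "dPao_max", target = "dPao_max"),
    list(param = "R_pv", output = "dPpa_max", target = "dPpa_max"))
  if (cfg$fix_valves)
    pairs <- purrr::discard(pairs, function(p)
      p$param %in% c("R_mt", "R_av", "R_tc", "R_pv"))
  # Venous identification, nested.  The venous elastances are paired
  # with the mean venous pressures (the pairing table's six-chamber
  # rows: the pulmonary-vein and vena cava pressures implied by the
  # measured valve closure times drive E_pu and E_vc); these are
  # strong, direct pairings that the inner joint loop converges
  # together with the cardio-arterial pairs.  The pressure targets
  # themselves are only estimates (a decoupled stage reads the venous
  # pressure at closure, not the beat mean), so an outer secant
  # refines each target from its closure-phase residual after the
  # inner loop has converged.
  check_pairs <- c(
    purrr::discard(pairs, function(p) isFALSE(p$check %||% TRUE)),
    list(list(param = "E_pu", output = "phi_mt", target = "phi_mt",
              tol = cfg$phase_tol),
         list(param = "E_vc", output = "phi_tc", target = "phi_tc",
              tol = cfg$phase_tol)))
  relations <- setNames(
    lapply(pairs, function(p)
      resolve_relation(p$param, p$output, params, "closed", cfg)),
    vapply(pairs, function(p) paste0(p$param, ":", p$output),
           character(1)))

  t_peak <- driver_peak_time(params$driL)
  meas <- c(spl, list(half_GEDV = spl$GEDV / 2,
                      phi_mt = closure_phase(spl$t_mt, t_peak, spl$T),
                      phi_tc = closure_phase(spl$t_tc, t_peak, spl$T)))

  sim_outs <- function(params, warm) {
    w <- try(steady_state_beat(params, f_s = cfg$f_s, mode = "closed",
                               init = warm), silent = TRUE)
    if (inherits(w, "try-error")) return(NULL)
    outs <- model_outputs(w, "closed", cfg)
    outs$phi_mt <- if (is.na(outs$t_mt)) NA_real_
      else closure_phase(outs$t_mt, t_peak, spl$T)
    outs$phi_tc <- if (is.na(outs$t_tc)) NA_real_
      else closure_phase(outs$t_tc, t_peak, spl$T)
    list(outs = outs, warm = attr(w, "final_state"))
  }

  it <- 0
  # inner engine: joint proportional-gain loop over all pairings at the
  # current venous pressure targets
  inner_converge <- function(params, warm, cap = cfg$max_inner) {
    fails <- 0
    stall <- 0L
    prev_worst <- Inf
    relax_state <- cfg$relax
    prev_params <- params
    res <- NULL
    outs <- NULL
    for (k in seq_len(cap)) {
      so <- sim_outs(params, warm)
      if (is.null(so)) {  # simulation failed: revert, damp, cold restart
        fails <- fails + 1
        if (fails > 5) break
        params <- prev_params
        warm <- NULL
        relax_state <- max(relax_state * cfg$damping, 0.05 * cfg$relax)
        next
      }
      outs <- so$outs
      warm <- so$warm
      it <<- it + 1
      res <- residual_table(outs, meas, check_pairs)
      inner <- res$residual_pct[!res$output %in% c("phi_mt", "phi_tc")]
      worst <- max(inner, na.rm = TRUE) / 100
      if (cfg$verbose)
        message(sprintf("[coupled] iter %d inner %.4g%%", k, 100 * worst))
      if (!is.finite(worst) || worst < cfg$inner_tol) break
      stall <- if (abs(worst - prev_worst) < 1e-6) stall + 1L else 0L
      if (stall >= 10L) break
      relax_state <- if (worst > prev_worst)
        max(relax_state * cfg$damping, 0.05 * cfg$relax)
      else min(cfg$relax, relax_state * 1.1)
      prev_worst <- worst
      prev_params <- params
      params <- apply_updates(params, pairs, outs, meas, relations,
                              relax_state, cfg$ratio_clamp)
    }
    list(params = params, warm = warm, res = res, outs = outs)
  }

  # outer: refine the venous pressure targets from the closure-phase
  # residuals (a higher venous level delays inflow-valve closure)
  phi_gaps <- function(st) {
    o <- c(st$outs$phi_mt, st$outs$phi_tc)
    if (anyNA(o)) return(c(NA_real_, NA_real_))
    log(c(meas$phi_mt, meas$phi_tc) / o)
  }
  state_score <- function(st, g) {
    if (is.null(st$res) || anyNA(g)) return(Inf)
    inner <- st$res$residual_pct[!st$res$output %in% c("phi_mt",
                                                       "phi_tc")]
    max(max(inner, na.rm = TRUE) / (100 * cfg$inner_tol),
        max(abs(g)) / cfg$phase_tol)
  }
  st <- inner_converge(params, warm)
  g <- phi_gaps(st)
  st_best <- st
  best_score <- state_score(st, g)
  ln_pu <- log(st$params$E_pu)
  ln_vc <- log(st$params$E_vc)
  b_pu <- log(param_bounds$E_pu)
  b_vc <- log(param_bounds$E_vc)
  slope <- c(0.3, 0.3)   # -d(gap)/d(ln E) starting guess, secant-refined
  scale <- 1
  bad_steps <- 0
  for (v_it in seq_len(12)) {
    if (is.null(st$res) || anyNA(g) ||
        max(abs(g)) < 0.5 * cfg$phase_tol) break
    step_pu <- min(max(scale * g[1] / slope[1], -log(1.3)), log(1.3))
    step_vc <- min(max(scale * g[2] / slope[2], -log(1.3)), log(1.3))
    ln_pu_new <- min(max(ln_pu + step_pu, b_pu[1]), b_pu[2])
    ln_vc_new <- min(max(ln_vc + step_vc, b_vc[1]), b_vc[2])
    if (abs(ln_pu_new - ln_pu) < 1e-6 &&
        abs(ln_vc_new - ln_vc) < 1e-6) break
    trial <- st$params
    trial$E_pu <- exp(ln_pu_new)
    trial$E_vc <- exp(ln_vc_new)
    st2 <- inner_converge(trial, st$warm, cap = 60)
    g2 <- phi_gaps(st2)
    if (cfg$verbose)
      message(sprintf(
        "[venous %d] E_pu %.4g E_vc %.4g gaps %.3g%% %.3g%% -> %.3g%% %.3g%%",
        v_it, exp(ln_pu_new), exp(ln_vc_new), 100 * g[1], 100 * g[2],
        100 * g2[1], 100 * g2[2]))
    if (is.null(st2$res) || anyNA(g2)) break
    if (state_score(st2, g2) < best_score) {
      st_best <- st2
      best_score <- state_score(st2, g2)
    }
    if (max(abs(g2)) > max(abs(g))) {
      # the step made the phases worse: revert, shorten, and give up
      # on the phases after repeated failures (they stay flagged)
      scale <- scale / 2
      if ((bad_steps <- bad_steps + 1) >= 3) break
      next
    }
    if (abs(ln_pu_new - ln_pu) > 1e-4 && is.finite(g2[1]))
      slope[1] <- min(max((g[1] - g2[1]) / (ln_pu_new - ln_pu), 0.05), 3)
    if (abs(ln_vc_new - ln_vc) > 1e-4 && is.finite(g2[2]))
      slope[2] <- min(max((g[2] - g2[2]) / (ln_vc_new - ln_vc), 0.05), 3)
    st <- st2
    ln_pu <- ln_pu_new
    ln_vc <- ln_vc_new
    g <- g2
    bad_steps <- 0
    scale <- min(1, scale * 1.5)
  }
  # final polish of the best visited state at the full iteration budget
  st <- st_best
  st_p <- inner_converge(st$params, st$warm)
  if (!is.null(st_p$res) &&
      state_score(st_p, phi_gaps(st_p)) <= best_score) st <- st_p
  params <- st$params
  res <- st$res
  outs <- st$outs
  converged <- FALSE
  if (!is.null(res)) {
    flag_tols <- ifelse(res$output %in% c("phi_mt", "phi_tc"),
                        cfg$phase_tol, cfg$outer_tol)
    norm <- res$residual_pct / (100 * flag_tols)
    converged <- !anyNA(norm) && max(norm) < 1
  }

  if (is.null(res)) {  # every coupled simulation failed
    res <- residual_table(list(), meas, check_pairs)
    nm <- c(stage_output_names("closed"), "LVEDV", "RVEDV", "P_lv_max",
            "P_rv_max")
    outs <- setNames(as.list(rep(NA_real_, length(nm))), nm)
    converged <- FALSE
  }
  structure(list(
    params = params, setpoints = as_tibble(spl), residuals = res,
    converged = converged, iterations = it,
    outputs = outs[c("LVEDV", "RVEDV", "P_lv_max", "P_rv_max", "GEDV",
                     "SV_lv", "SV_rv", "MAP", "MPAP", "PP_ao", "PP_pa",
                     "t_mt", "t_tc")],
    venous_targets = c(P_pu = P_pu_target, P_vc = P_vc_target)),
    class = "cvs_fit")
}

#' Identify a subject-specific model from one set-point record
#'
#' The full staged pipeline: the systemic submodel is identified first,
#' then the pulmonary submodel, and the two are joined through septal and
#' pericardial coupling and re-identified in the coupled context until
#' every matched output reproduces its measurement within the inner
#' tolerance.  When a full starting parameter set is supplied the
#' decoupled bootstrap is skipped and the coupled stage starts from it
#' directly (so initialising at a model's own parameters terminates
#' immediately).
#'
#' @inheritParams identify_submodel
#' @param init Optional `cvs_params` used as the coupled-stage start.
#' @return A `cvs_fit`: identified `params`, per-output `residuals` in
#'   percent, modelled validation `outputs` (LVEDV, RVEDV, maximum
#'   ventricular pressures, ...), convergence flag and iteration count.
#' @export
identify_model <- function(sp, cfg = identification_config(),
                           driver = NULL, init = NULL) {
  if (!is.null(init)) {
    fit <- identify_sixchamber(NULL, NULL, sp, cfg, init = init)
    return(fit)
  }
  sys <- identify_submodel(sp, "systemic", driver = driver, cfg = cfg)
  pul <- identify_submodel(sp, "pulmonary", driver = driver, cfg = cfg)
  fit <- identify_sixchamber(sys, pul, sp, cfg)
  fit$systemic_stage <- sys[c("estimates", "residuals", "converged",
                              "iterations")]
  fit$pulmonary_stage <- pul[c("estimates", "residuals", "converged",
                               "iterations")]
  fit
}

#' Identify a subject's series of timepoints
#'
#' Identifies a model for each timepoint independently, averages the four
#' valve resistances over the converged timepoints, and re-identifies all
#' remaining parameters per timepoint with the valves fixed at the
#' averages.  Timepoints that fail to converge are carried with their
#' flags and excluded from the valve average.
#'
#' @param sps A list of `cvs_setpoints` rows (or a tibble with one row
#'   per timepoint), ordered in time.
#' @param cfg An [identification_config()].
#' @param labels Optional timepoint labels (default `T0`, `T30`, ...).
#' @return An object of class `cvs_series`: `fits` (first pass),
#'   `refits` (valve-averaged pass), `valve_resistances` (named means).
#' @export
identify_subject <- function(sps, cfg = identification_config(),
                             labels = NULL) {
  if (inherits(sps, "data.frame")) {
    sps <- lapply(seq_len(nrow(sps)), function(i) sps[i, ])
  }
  stopifnot(length(sps) >= 1)
  if (is.null(labels)) labels <- paste0("T", 30 * (seq_along(sps) - 1))
  fits <- purrr::map(sps, identify_model, cfg = cfg)
  names(fits) <- labels
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  use <- if (any(ok)) fits[ok] else fits
  valves <- c("R_mt", "R_av", "R_tc", "R_pv")
  vavg <- vapply(valves, function(v)
    mean(vapply(use, function(f) f$params[[v]], numeric(1))), numeric(1))
  cfg2 <- cfg
  cfg2$fix_valves <- TRUE
  refits <- purrr::map2(sps, fits, function(sp, f) {
    p <- f$params
    for (v in valves) p[[v]] <- vavg[[v]]
    identify_model(sp, cfg = cfg2, init = p)
  })
  names(refits) <- labels
  structure(list(fits = fits, refits = refits, valve_resistances = vavg,
                 labels = labels, converged = ok),
            class = "cvs_series")
}

#' Arterial (pulmonary) afterload elastance
#'
#' The afterload on the right ventricle expressed as an effective
#' arterial elastance: the sum of the pulmonary valve and pulmonary
#' vascular resistances divided by the heartbeat period,
#' `E_a = (R_pv + R_pul) / T`.
#'
#' @param R_pv Pulmonary valve resistance, mmHg s/mL.
#' @param R_pul Pulmonary vascular resistance, mmHg s/mL.
#' @param T Heartbeat period, s.
#' @return `E_a` in mmHg/mL.
#' @export
#' @examples
#' afterload_metric(0.03, 0.4, 0.5)  # 0.86
afterload_metric <- function(R_pv, R_pul, T) {
  if (any(T <= 0)) stop("period T must be positive")
  if (any(c(R_pv, R_pul) < 0)) stop("resistances must be nonnegative")
  (R_pv + R_pul) / T
}

#' @export
print.cvs_fit <- function(x, ...) {
  cat(sprintf("<cvs_fit> %s after %d iterations (worst residual %.3g%%)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(x$residuals$residual_pct, na.rm = TRUE)))
  print(x$params)
  invisible(x)
}

#' @export
print.cvs_series <- function(x, ...) {
  cat(sprintf("<cvs_series> %d timepoints (%d converged)\n",
              length(x$fits), sum(x$converged)))
  cat("  averaged valve resistances:",
      paste(sprintf("%s=%.4g", names(x$valve_resistances),
                    x$valve_resistances), collapse = " "), "\n")
  invisible(x)
}
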