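#' Ventricular free-wall pressure
#'
#' Pressure generated by an actively elastic wall, blending the linear
#' end-systolic relation `E_es * (V - V_d)` and the exponential
#' end-diastolic relation `P_0 * (exp(lambda * (V - V_0)) - 1)` by the
#' instantaneous activation `dri`:
#'
#' `P = dri * E_es * (V - V_d) + (1 - dri) * P_0 * (exp(lambda * (V - V_0)) - 1)`
#'
#' @param V Wall volume in mL (free-wall volume for a ventricle).
#' @param dri Activation in \[0, 1\].
#' @param E_es End-systolic elastance, mmHg/mL.
#' @param V_d ESPVR dead-space volume, mL.
#' @param P_0 EDPVR pressure scale, mmHg.
#' @param lambda EDPVR exponent, 1/mL.
#' @param V_0 EDPVR volume offset, mL.
#' @return Pressure in mmHg.
#' @export
#' @examples
#' ventricle_pressure(73, dri = 1, E_es = 2, V_d = 23)  # 100 mmHg
ventricle_pressure <- function(V, dri, E_es, V_d = 23, P_0 = 0,
                               lambda = 0, V_0 = 0) {
  stopifnot(all(dri >= 0 & dri <= 1))
  dri * E_es * (V - V_d) + (1 - dri) * P_0 * expm1(lambda * (V - V_0))
}

#' Passive chamber pressure
#'
#' The non-cardiac chambers are passively elastic: pressure is linear in
#' volume above the unstressed volume, `P = E * (V - V_d)`.
#'
#' @param V Chamber volume, mL.
#' @param E Chamber elastance, mmHg/mL.
#' @param V_d Unstressed volume, mL.
#' @return Pressure in mmHg.
#' @export
passive_pressure <- function(V, E, V_d = 0) E * (V - V_d)

#' Septal volume from the free-wall pressure balance
#'
#' The ventricular interaction is carried by the septum: its deflection
#' volume `V_spt` satisfies the implicit balance
#' `P_spt(V_spt) = P_lvf(V_lv - V_spt) - P_rvf(V_rv + V_spt)`,
#' where each wall follows the active elastance law of
#' [ventricle_pressure()] and the septum shares the left ventricular
#' activation.  Both sides are monotone in `V_spt` with opposite sense, so
#' the root is unique; it is solved to an absolute tolerance of 1e-6 mL.
#'
#' @param V_lv,V_rv Ventricular (cavity) volumes, mL.
#' @param driL,driR Left/right activation values in \[0, 1\].
#' @param params A `cvs_params` object.
#' @return Septal volume in mL (positive towards the right ventricle).
#' @export
septum_volume <- function(V_lv, V_rv, driL, driR, params) {
  stopifnot(inherits(params, "cvs_params"))
  cpp_septum_volume(params_for_cpp(params), V_lv, V_rv, driL, driR)
}

params_for_cpp <- function(params) {
  p <- unclass(params)
  p$driL <- unclass(p$driL)
  p$driR <- unclass(p$driR)
  p
}

#' Chamber pressures at a given state
#'
#' Computes all six chamber pressures from the chamber volumes.  The
#' ventricular pressures add the pericardial pressure
#' `P_pcd = P_0_pcd * (exp(lambda_pcd * (V_lv + V_rv - V_0_pcd)) - 1)` and
#' the intrathoracic pressure `P_th` to the free-wall pressures; the
#' passive chambers follow [passive_pressure()].
#'
#' @param state Named numeric vector or list with `V_lv`, `V_ao`, `V_vc`,
#'   `V_rv`, `V_pa`, `V_pu` (mL).
#' @param t Time in seconds (sets the activation via the drivers).
#' @param params A `cvs_params` object.
#' @return Named list with `P_lv`, `P_ao`, `P_vc`, `P_rv`, `P_pa`,
#'   `P_pu`, plus `V_spt` and `P_pcd` (mmHg, mL).
#' @export
compute_pressures <- function(state, t, params) {
  stopifnot(inherits(params, "cvs_params"))
  s <- as.list(state)
  dL <- driver_value(params$driL, t)
  dR <- driver_value(params$driR, t)
  V_spt <- septum_volume(s$V_lv, s$V_rv, dL, dR, params)
  P_pcd <- params$P_0_pcd *
    expm1(params$lambda_pcd * (s$V_lv + s$V_rv - params$V_0_pcd))
  P_lvf <- ventricle_pressure(s$V_lv - V_spt, dL, params$E_es_lvf,
                              params$V_d_lvf, params$P_0_lvf,
                              params$lambda_lvf, params$V_0_lvf)
  P_rvf <- ventricle_pressure(s$V_rv + V_spt, dR, params$E_es_rvf,
                              params$V_d_rvf, params$P_0_rvf,
                              params$lambda_rvf, params$V_0_rvf)
  list(
    P_lv = P_lvf + P_pcd + params$P_th,
    P_ao = passive_pressure(s$V_ao, params$E_ao, params$V_d_ao),
    P_vc = passive_pressure(s$V_vc, params$E_vc, params$V_d_vc),
    P_rv = P_rvf + P_pcd + params$P_th,
    P_pa = passive_pressure(s$V_pa, params$E_pa, params$V_d_pa),
    P_pu = passive_pressure(s$V_pu, params$E_pu, params$V_d_pu),
    V_spt = V_spt, P_pcd = P_pcd
  )
}

#' Flows between chambers
#'
#' The four heart valves are pressure-gated ideal diodes (inertances are
#' zero in this formulation): flow is the forward pressure drop over the
#' valve resistance, clamped at zero.  The systemic and pulmonary
#' vascular flows are Ohmic and unclamped.
#'
#' @param pressures Named list as returned by [compute_pressures()].
#' @param params A `cvs_params` object.
#' @return Named list with `Q_mt`, `Q_av`, `Q_sys`, `Q_tc`, `Q_pv`,
#'   `Q_pul` in mL/s.
#' @export
compute_flows <- function(pressures, params) {
  stopifnot(inherits(params, "cvs_params"))
  p <- pressures
  list(
    Q_mt  = max(0, (p$P_pu - p$P_lv) / params$R_mt),
    Q_av  = max(0, (p$P_lv - p$P_ao) / params$R_av),
    Q_sys = (p$P_ao - p$P_vc) / params$R_sys,
    Q_tc  = max(0, (p$P_vc - p$P_rv) / params$R_tc),
    Q_pv  = max(0, (p$P_rv - p$P_pa) / params$R_pv),
    Q_pul = (p$P_pa - p$P_pu) / params$R_pul
  )
}

#' Time derivatives of the chamber volumes
#'
#' Volume balance of the closed loop: each chamber gains its inflow and
#' loses its outflow, so the six derivatives sum to zero at every
#' evaluation.  In submodel mode (`mode = "systemic"` or `"pulmonary"`)
#' the upstream source chamber is replaced by the fixed pressure `P_pu`
#' (systemic) or `P_vc` (pulmonary) and only the two remaining chamber
#' volumes evolve.
#'
#' @inheritParams compute_pressures
#' @param mode `"closed"` (default), `"systemic"`, or `"pulmonary"`.
#' @return Named list of `dV/dt` entries in mL/s.
#' @export
cvs_derivatives <- function(state, t, params, mode = "closed") {
  mode <- match.arg(mode, c("closed", "systemic", "pulmonary"))
  s <- as.list(state)
  if (mode == "closed") {
    pr <- compute_pressures(s, t, params)
    q <- compute_flows(pr, params)
    return(list(V_lv = q$Q_mt - q$Q_av, V_ao = q$Q_av - q$Q_sys,
                V_vc = q$Q_sys - q$Q_tc, V_rv = q$Q_tc - q$Q_pv,
                V_pa = q$Q_pv - q$Q_pul, V_pu = q$Q_pul - q$Q_mt))
  }
  if (mode == "systemic") {
    dL <- driver_value(params$driL, t)
    P_lv <- ventricle_pressure(s$V_lv, dL, params$E_es_lvf, params$V_d_lvf,
                               params$P_0_lvf, params$lambda_lvf,
                               params$V_0_lvf)
    P_ao <- passive_pressure(s$V_ao, params$E_ao, params$V_d_ao)
    Q_mt <- max(0, (params$P_pu - P_lv) / params$R_mt)
    Q_av <- max(0, (P_lv - P_ao) / params$R_av)
    Q_sys <- (P_ao - params$P_vc) / params$R_sys
    return(list(V_lv = Q_mt - Q_av, V_ao = Q_av - Q_sys))
  }
  dR <- driver_value(params$driR, t)
  P_rv <- ventricle_pressure(s$V_rv, dR, params$E_es_rvf, params$V_d_rvf,
                             params$P_0_rvf, params$lambda_rvf,
                             params$V_0_rvf)
  P_pa <- passive_pressure(s$V_pa, params$E_pa, params$V_d_pa)
  Q_tc <- max(0, (params$P_vc - P_rv) / params$R_tc)
  Q_pv <- max(0, (P_rv - P_pa) / params$R_pv)
  Q_pul <- (P_pa - params$P_pu) / params$R_pul
  list(V_rv = Q_tc - Q_pv, V_pa = Q_pv - Q_pul)
}
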