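#' Fixed constants of the six-chamber circulation model
#'
#' Returns the constants that are held fixed during parameter
#' identification: the exponential end-diastolic pressure-volume
#' relationship (EDPVR) constants of both ventricular free walls, the
#' ventricular dead-space volumes (the end-systolic pressure-volume
#' relationship, ESPVR, intercepts), the septal and pericardial constants,
#' the intrathoracic pressure, the unstressed volumes of the four passive
#' chambers, and the (zero) valve inertances.
#'
#' Units are mmHg, mL, s throughout; elastances in mmHg/mL, EDPVR
#' exponents in 1/mL.
#'
#' @return Named list of model constants.
#' @export
#' @examples
#' cvs_constants()$V_d_lvf  # ventricular dead space, mL
cvs_constants <- function() {
  list(
    # ventricular free walls: EDPVR scale/exponent, ESPVR dead space
    P_0_lvf = 0, lambda_lvf = 0.033, V_d_lvf = 23, V_0_lvf = 0,
    P_0_rvf = 0, lambda_rvf = 0.023, V_d_rvf = 23, V_0_rvf = 0,
    # septum
    V_d_spt = 2, V_0_spt = 2, lambda_spt = 0.435, P_0_spt = 1.1101,
    E_es_spt = 48.7540,
    # pericardium
    P_0_pcd = 0.5003, V_0_pcd = 200, lambda_pcd = 0.03,
    # thorax
    P_th = 0,
    # passive chamber unstressed volumes
    V_d_ao = 0, V_d_vc = 0, V_d_pa = 0, V_d_pu = 0,
    # valve inertances (ignored in this formulation)
    L_mt = 0, L_av = 0, L_tc = 0, L_pv = 0
  )
}

#' Initial parameter values for the systemic submodel
#'
#' Starting values for the iterative identification of the systemic
#' circulation: pulmonary vein (source) pressure, mitral and aortic valve
#' resistances, left ventricular end-systolic elastance, aortic elastance,
#' systemic vascular resistance, and the vena cava (sink) pressure.
#'
#' @return Named list of starting values (mmHg, mmHg s/mL, mmHg/mL).
#' @export
systemic_init <- function() {
  list(P_pu = 5, R_mt = 0.05, E_es_lvf = 2, R_av = 0.04,
       E_ao = 2.5, R_sys = 2.5, P_vc = 5)
}

#' Initial parameter values for the pulmonary submodel
#'
#' @return Named list of starting values for the pulmonary circulation:
#'   vena cava (source) pressure, tricuspid and pulmonary valve
#'   resistances, right ventricular end-systolic elastance, pulmonary
#'   artery elastance, pulmonary vascular resistance, and the pulmonary
#'   vein (sink) pressure.
#' @export
pulmonary_init <- function() {
  list(P_vc = 5, R_tc = 0.04, E_es_rvf = 0.8, R_pv = 0.03,
       E_pa = 2.1, R_pul = 0.4, P_pu = 5)
}

#' Assemble a full circulation parameter set
#'
#' Builds the complete parameter list for the six-chamber model (or either
#' decoupled submodel) from the fixed constants ([cvs_constants()]), the
#' identifiable parameters, the driver pair, and the total stressed
#' volume.  Any subset can be overridden by name.
#'
#' @param ... Named overrides of any parameter (e.g. `R_sys = 1.8`).
#' @param heart_rate Heart rate in beats per minute; sets the common
#'   driver period unless explicit drivers are supplied.
#' @param driL,driR Driver functions (see [cvs_driver()]); default is the
#'   parametric pulse at the given heart rate for both ventricles.
#' @param V_total Total stressed blood volume in mL distributed over the
#'   six chambers in closed-loop simulation.
#' @return An object of class `cvs_params`: a named list with all model
#'   constants, identifiable parameters, drivers, and `V_total`.
#' @export
#' @examples
#' p <- cvs_params(heart_rate = 120, R_sys = 2.0)
#' p$R_sys
cvs_params <- function(..., heart_rate = 120, driL = NULL, driR = NULL,
                       V_total = 280) {
  period <- 60 / heart_rate
  if (is.null(driL)) driL <- cvs_driver(period)
  if (is.null(driR)) driR <- cvs_driver(period)
  p <- c(cvs_constants(), systemic_init(),
         pulmonary_init()[c("R_tc", "E_es_rvf", "R_pv", "E_pa", "R_pul")],
         list(E_vc = 0.12, E_pu = 0.12))
  p$driL <- driL
  p$driR <- driR
  p$V_total <- V_total
  p$heart_rate <- heart_rate
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(p)))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, dots)
  }
  validate_cvs_params(p)
  structure(p, class = "cvs_params")
}

validate_cvs_params <- function(p) {
  res <- c("R_mt", "R_av", "R_sys", "R_tc", "R_pv", "R_pul")
  for (r in res)
    if (!is.numeric(p[[r]]) || p[[r]] <= 0)
      stop("resistance ", r, " must be positive")
  ela <- c("E_es_lvf", "E_es_rvf", "E_es_spt", "E_ao", "E_vc", "E_pa", "E_pu")
  for (e in ela)
    if (!is.numeric(p[[e]]) || p[[e]] <= 0)
      stop("elastance ", e, " must be positive")
  for (nm in c("lambda_lvf", "lambda_rvf", "lambda_spt", "lambda_pcd",
               "P_0_lvf", "P_0_rvf", "P_0_spt", "P_0_pcd",
               "V_d_lvf", "V_d_rvf"))
    if (p[[nm]] < 0) stop(nm, " must be nonnegative")
  if (p$driL$period != p$driR$period)
    stop("left and right drivers must share one period")
  invisible(p)
}

#' @export
print.cvs_params <- function(x, ...) {
  cat("<cvs_params> six-chamber circulation parameter set\n")
  cat(sprintf("  heart rate %.4g bpm (period %.4g s), V_total %.4g mL\n",
              x$heart_rate, x$driL$period, x$V_total))
  show <- c("E_es_lvf", "E_es_rvf", "R_sys", "R_pul", "E_ao", "E_pa",
            "R_mt", "R_av", "R_tc", "R_pv", "E_vc", "E_pu")
  vals <- vapply(show, function(n) x[[n]], numeric(1))
  cat("  ", paste(sprintf("%s=%.4g", show, vals), collapse = " "), "\n")
  invisible(x)
}

#' Serialize a parameter set to a flat configuration file
#'
#' Writes (or reads back) the scalar entries of a `cvs_params` object as a
#' flat key/value YAML or JSON file keyed by the standard symbol names
#' (`E_es_lvf`, `R_sys`, `lambda_pcd`, ...).  Parametric drivers are
#' stored by their period, peak time and width; sampled drivers by their
#' curve values.
#'
#' @param params A `cvs_params` object.
#' @param path Output file; extension `.yaml`/`.yml` or `.json` selects
#'   the format.
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns a `cvs_params` object.
#' @export
write_params_config <- function(params, path) {
  x <- unclass(params)
  x$driL <- unclass(x$driL)
  x$driR <- unclass(x$driR)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (d in c("driL", "driR")) {
    x[[d]]$values <- as.numeric(x[[d]]$values)
    class(x[[d]]) <- "cvs_driver"
  }
  p <- structure(x, class = "cvs_params")
  validate_cvs_params(p)
  p
}
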