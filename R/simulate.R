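mode_code <- function(mode) {
  mode <- match.arg(mode, c("closed", "systemic", "pulmonary"))
  c(closed = 0L, systemic = 1L, pulmonary = 2L)[[mode]]
}

#' Default initial chamber volumes
#'
#' A physiologically scaled split of the total stressed volume used to
#' start closed-loop integration, or nominal ventricular/arterial volumes
#' for the decoupled submodels.
#'
#' @param params A `cvs_params` object.
#' @param mode Simulation mode.
#' @return Named numeric vector of chamber volumes in mL.
#' @export
initial_state <- function(params, mode = "closed") {
  mode <- match.arg(mode, c("closed", "systemic", "pulmonary"))
  if (mode == "systemic") return(c(V_lv = 100, V_ao = 100 / params$E_ao))
  if (mode == "pulmonary") return(c(V_rv = 100, V_pa = 25 / params$E_pa))
  # split V_total with nominal pressures in the passive chambers
  v <- c(V_lv = 95, V_ao = 90 / params$E_ao, V_vc = 5 / params$E_vc,
         V_rv = 95, V_pa = 20 / params$E_pa, V_pu = 5 / params$E_pu)
  extra <- params$V_total - sum(v)
  v[["V_vc"]] <- max(1, v[["V_vc"]] + extra)  # vena cava takes the slack
  v * (params$V_total / sum(v))
}

waveform_tibble <- function(samples, f_s, period = NULL, converged = NA,
                            beats_run = NA) {
  w <- as_tibble(as.data.frame(samples))
  structure(w, class = c("cvs_waveform", class(w)), f_s = f_s,
            period = period, converged = converged, beats_run = beats_run)
}

#' Simulate the circulation model
#'
#' Integrates the chamber-volume ODE system over a whole number of
#' heartbeats with an adaptive Dormand-Prince (RK45) scheme (relative and
#' absolute tolerance 1e-7 by default) and samples all pressures, volumes
#' and flows on a uniform grid.
#'
#' @param params A `cvs_params` object.
#' @param n_beats Number of beats to simulate (>= 1).
#' @param f_s Sampling frequency in Hz.
#' @param mode `"closed"` for the six-chamber loop, `"systemic"` or
#'   `"pulmonary"` for a decoupled submodel with fixed source pressure.
#' @param init Initial chamber volumes; defaults to [initial_state()].
#' @param rtol,atol Solver tolerances.
#' @return A `cvs_waveform` tibble with columns `t`, chamber volumes,
#'   `V_spt`, all pressures, and all flows; beat onsets fall at multiples
#'   of the period.  The attribute `f_s` records the sampling rate.
#' @export
#' @examples
#' w <- simulate_cvs(cvs_params(), n_beats = 2, mode = "systemic")
#' range(w$P_ao)
simulate_cvs <- function(params, n_beats = 1, f_s = 200, mode = "closed",
                         init = NULL, rtol = 1e-7, atol = 1e-7) {
  stopifnot(inherits(params, "cvs_params"))
  if (n_beats < 1) stop("n_beats must be >= 1")
  if (f_s <= 0) stop("f_s must be positive")
  if (is.null(init)) init <- initial_state(params, mode)
  out <- cpp_simulate(params_for_cpp(params), mode_code(mode),
                      as.numeric(init), as.integer(n_beats), f_s, rtol, atol)
  waveform_tibble(out$samples, f_s, period = params$driL$period)
}

#' Periodic steady-state beat
#'
#' Integrates beat by beat until the chamber volumes at beat onset change
#' by less than `tol_ml` (default 0.01 mL) between consecutive beats, or
#' `max_beats` is reached, and returns the final beat sampled at `f_s`.
#' Non-convergence is reported through the `converged` attribute rather
#' than as an error.
#'
#' @inheritParams simulate_cvs
#' @param tol_ml Beat-to-beat volume tolerance in mL.
#' @param max_beats Maximum number of beats to run.
#' @return A one-beat `cvs_waveform` tibble with attributes `converged`,
#'   `beats_run`, and `final_state` (the chamber volumes at the end of
#'   the returned beat, usable as a warm start).
#' @export
steady_state_beat <- function(params, f_s = 200, mode = "closed",
                              init = NULL, tol_ml = 0.01, max_beats = 300,
                              rtol = 1e-7, atol = 1e-7) {
  stopifnot(inherits(params, "cvs_params"))
  if (is.null(init)) init <- initial_state(params, mode)
  out <- cpp_steady_state(params_for_cpp(params), mode_code(mode),
                          as.numeric(init), f_s, tol_ml,
                          as.integer(max_beats), rtol, atol)
  w <- waveform_tibble(out$samples, f_s, period = params$driL$period,
                       converged = out$converged,
                       beats_run = out$beats_run)
  attr(w, "final_state") <- out$state
  w
}

#' @export
print.cvs_waveform <- function(x, ...) {
  conv <- attr(x, "converged")
  cat(sprintf("<cvs_waveform> %d samples at %g Hz%s\n", nrow(x),
              attr(x, "f_s"),
              if (!is.na(conv)) paste0(", steady-state converged: ", conv)
              else ""))
  NextMethod()
}

#' Waveform plot
#'
#' Plots the pressure (and optionally volume and flow) traces of a
#' simulated or loaded waveform set, one facet per signal.
#'
#' @param object A `cvs_waveform` tibble.
#' @param signals Character vector of columns to plot; default all
#'   non-missing pressures and ventricular volumes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvs_waveform <- function(object,
                                  signals = c("P_ao", "P_pa", "P_lv",
                                              "P_rv", "V_lv", "V_rv"),
                                  ...) {
  signals <- intersect(signals, names(object))
  signals <- signals[vapply(signals,
                            function(s) !all(is.na(object[[s]])), logical(1))]
  long <- tidyr::pivot_longer(object[, c("t", signals)], -"t",
                              names_to = "signal", values_to = "value")
  long$signal <- factor(long$signal, levels = signals)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~signal, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
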