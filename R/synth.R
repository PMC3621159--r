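#' Septic-shock trajectory configuration
#'
#' Describes the phenomenological parameter trends imposed on a virtual
#' subject after endotoxin infusion: a fall in systemic vascular
#' resistance reaching its full depth two hours after infusion onset, a
#' concurrent rise in pulmonary vascular resistance, mild tachycardia,
#' and (optionally) a responder pattern in which systemic resistance
#' recovers towards baseline after the intervention.  Trends are logistic
#' in time between the 30 and 120 minute timepoints.
#'
#' @param n_timepoints Number of 30-minute timepoints (default 9:
#'   T0...T240).
#' @param spacing_min Spacing between timepoints in minutes.
#' @param r_sys_drop Fractional drop of systemic resistance reached at
#'   the 120-minute timepoint (default 0.42).
#' @param r_pul_rise Fractional rise of pulmonary resistance (default
#'   0.5).
#' @param responder If `TRUE`, systemic resistance relaxes back towards
#'   baseline after the trough.
#' @param recovery Fraction of the drop recovered by the final timepoint
#'   for responders.
#' @param hr_rise Fractional heart-rate rise accompanying the shock.
#' @param noise_sd Multiplicative Gaussian noise SD applied per sample to
#'   each measured signal (0 disables).
#' @param rv_factor Right-ventricular volume amplitude scaling emulating
#'   conductance-catheter underestimation (1 = off).
#' @param beats Beats recorded per timepoint.
#' @param f_s Sampling frequency, Hz.
#' @return A list of class `cvs_sepsis_config`.
#' @export
sepsis_config <- function(n_timepoints = 9, spacing_min = 30,
                          r_sys_drop = 0.42, r_pul_rise = 0.5,
                          responder = FALSE, recovery = 0.8,
                          hr_rise = 0.10, noise_sd = 0.03, rv_factor = 1,
                          beats = 8, f_s = 200) {
  stopifnot(n_timepoints >= 1, r_sys_drop >= 0, r_sys_drop < 1,
            r_pul_rise >= 0, rv_factor > 0, rv_factor <= 1)
  structure(as.list(environment()), class = "cvs_sepsis_config")
}

#' Sample a virtual-subject baseline
#'
#' Draws the ten staged-identification parameters uniformly within +/-30
#' percent of the standard initial tables, with heart rate in 80-160 bpm,
#' keeping the model constants fixed.  The total stressed volume and the
#' venous elastances are held at package nominals (280 mL, 0.12 mmHg/mL):
#' neither is observable from the identification measurement set, so both
#' are treated as population constants rather than subject-level
#' variables.  The right
#' ventricular elastance is then solved (bisection on its +/-30 percent
#' range) so that the two end diastolic volumes balance at steady state:
#' healthy ventricles operate in series at equal stroke volume and hold
#' near-equal end diastolic volumes (the porcine cohort medians differ by
#' under five percent), and the global end diastolic volume only
#' constrains their sum during identification.  Draws whose closed-loop
#' steady state fails a physiological screen (mean aortic pressure 50-130
#' mmHg, stroke volume 20-60 mL) are rejected.
#'
#' @param seed Integer seed; a fixed seed reproduces the subject.
#' @param max_draws Rejection budget before giving up.
#' @param balance_tol Acceptable deviation of the left ventricular share
#'   of the global end diastolic volume from one half.
#' @return An object of class `cvs_subject` with elements `params`
#'   (baseline `cvs_params`), `seed`, `screen` (the accepted MAP, SV and
#'   left ventricular volume share), and `draws` (number of attempts).
#' @export
sample_baseline <- function(seed, max_draws = 200, balance_tol = 0.005) {
  set.seed(seed)
  nominal <- c(systemic_init()[c("R_mt", "E_es_lvf", "R_av", "E_ao",
                                 "R_sys")],
               pulmonary_init()[c("R_tc", "E_es_rvf", "R_pv", "E_pa",
                                  "R_pul")])
  lv_share <- function(w) max(w$V_lv) / (max(w$V_lv) + max(w$V_rv))
  for (draw in seq_len(max_draws)) {
    fac <- runif(length(nominal), 0.7, 1.3)
    vals <- purrr::map2(nominal, fac, `*`)
    hr <- runif(1, 80, 160)
    params <- do.call(cvs_params,
                      c(vals, list(heart_rate = hr)))
    # balance the end diastolic volumes via E_es_rvf (share falls as
    # E_es_rvf rises); keep the solution inside the +/-30 percent band
    lo <- 0.7 * nominal$E_es_rvf
    hi <- 1.3 * nominal$E_es_rvf
    w <- NULL
    ok <- FALSE
    for (k in seq_len(25)) {
      params$E_es_rvf <- sqrt(lo * hi)
      w <- try(steady_state_beat(params), silent = TRUE)
      if (inherits(w, "try-error") || !isTRUE(attr(w, "converged"))) break
      s <- lv_share(w)
      if (abs(s - 0.5) < balance_tol) { ok <- TRUE; break }
      if (s > 0.5) hi <- params$E_es_rvf else lo <- params$E_es_rvf
      if (hi / lo < 1.001) break  # balance unreachable within the band
    }
    if (!ok) next
    map <- waveform_mean(w$P_ao)
    sv <- stroke_volume(w$V_lv, w$V_rv)
    if (map >= 50 && map <= 130 && sv >= 20 && sv <= 60) {
      return(structure(list(params = params, seed = seed,
                            screen = c(MAP = map, SV = sv,
                                       lv_share = lv_share(w)),
                            draws = draw),
                       class = "cvs_subject"))
    }
  }
  stop("rejection budget exhausted: no physiological baseline in ",
       max_draws, " draws (seed ", seed, ")")
}

#' @export
print.cvs_subject <- function(x, ...) {
  cat(sprintf(
    "<cvs_subject> seed %d (accepted draw %d): MAP %.1f mmHg, SV %.1f mL\n",
    x$seed, x$draws, x$screen[["MAP"]], x$screen[["SV"]]))
  print(x$params)
  invisible(x)
}

# logistic trend shape: 0 at the 30-min timepoint, 1 at the 120-min one
sepsis_shape <- function(t_min) {
  l <- function(t) stats::plogis((t - 75) / 15)
  s <- (l(pmin(pmax(t_min, 30), 120)) - l(30)) / (l(120) - l(30))
  pmin(pmax(s, 0), 1)
}

#' Ground-truth parameter trajectory of a septic virtual subject
#'
#' Applies the configured multiplicative trends to the baseline
#' parameters at each timepoint: systemic resistance falls to
#' `(1 - r_sys_drop)` of baseline at the 120-minute timepoint, pulmonary
#' resistance rises by `r_pul_rise`, heart rate rises by `hr_rise`, and
#' the ventricular contractilities are held constant.  Responder
#' subjects recover a configurable fraction of the systemic-resistance
#' drop by the final timepoint.
#'
#' @param subject A `cvs_subject` from [sample_baseline()].
#' @param cfg A [sepsis_config()].
#' @return A list of per-timepoint `cvs_params`, named `T0`, `T30`, ...;
#'   the attribute `trends` carries the multiplier table.
#' @export
septic_trajectory <- function(subject, cfg = sepsis_config()) {
  stopifnot(inherits(subject, "cvs_subject"))
  t_min <- cfg$spacing_min * (seq_len(cfg$n_timepoints) - 1)
  s <- sepsis_shape(t_min)
  m_rsys <- 1 - cfg$r_sys_drop * s
  if (cfg$responder) {
    rcv <- pmin(pmax((t_min - 120) / 120, 0), 1) * cfg$recovery
    m_rsys <- 1 - cfg$r_sys_drop * s * (1 - rcv)
  }
  m_rpul <- 1 + cfg$r_pul_rise * s
  m_hr <- 1 + cfg$hr_rise * s
  base <- subject$params
  traj <- purrr::pmap(list(m_rsys, m_rpul, m_hr), function(a, b, h) {
    p <- base
    p$R_sys <- base$R_sys * a
    p$R_pul <- base$R_pul * b
    hr <- base$heart_rate * h
    p$heart_rate <- hr
    p$driL <- cvs_driver(60 / hr)
    p$driR <- cvs_driver(60 / hr)
    p
  })
  names(traj) <- paste0("T", t_min)
  attr(traj, "trends") <- tibble(t_min = t_min, R_sys_mult = m_rsys,
                                 R_pul_mult = m_rpul, hr_mult = m_hr)
  traj
}

add_measurement_noise <- function(w, sd, rv_factor = 1) {
  measured <- intersect(c("P_ao", "P_pa", "P_lv", "V_lv", "P_rv", "V_rv"),
                        names(w))
  if (rv_factor < 1 && "V_rv" %in% names(w)) {
    m <- mean(w$V_rv)
    w$V_rv <- m + rv_factor * (w$V_rv - m)
  }
  if (sd > 0) {
    for (col in measured)
      w[[col]] <- w[[col]] * (1 + rnorm(nrow(w), 0, sd))
  }
  w
}

#' Generate a measured dataset for a virtual subject
#'
#' Simulates each timepoint of the subject's septic trajectory to its
#' periodic steady state, records the configured number of beats at the
#' sampling frequency, applies multiplicative measurement noise to the
#' measured signals (aortic, pulmonary artery and ventricular pressures,
#' ventricular volumes) and the optional right-ventricular amplitude
#' bias, and extracts the convergence set points from each record.  The
#' noiseless modelled values are kept as ground truth.  Timepoints whose
#' steady-state search fails are flagged and omitted.
#'
#' @param subject A `cvs_subject`.
#' @param cfg A [sepsis_config()].
#' @param seed Seed for the measurement noise.
#' @param dir Optional directory; when given, per-timepoint waveform CSVs,
#'   set-point JSONs and a `truth.json` are written there.
#' @return A list of class `cvs_dataset` with per-timepoint elements
#'   `waveforms` (noisy `cvs_waveform`), `setpoints`, `truth` (true
#'   parameters and true model outputs), and `failed` (labels of omitted
#'   timepoints).
#' @export
generate_dataset <- function(subject, cfg = sepsis_config(), seed = 1,
                             dir = NULL) {
  stopifnot(inherits(subject, "cvs_subject"))
  set.seed(seed)
  traj <- septic_trajectory(subject, cfg)
  out <- list(waveforms = list(), setpoints = list(), truth = list(),
              failed = character())
  for (lbl in names(traj)) {
    p <- traj[[lbl]]
    ss <- try(steady_state_beat(p, f_s = cfg$f_s), silent = TRUE)
    if (inherits(ss, "try-error") || !isTRUE(attr(ss, "converged"))) {
      out$failed <- c(out$failed, lbl)
      next
    }
    w <- simulate_cvs(p, n_beats = cfg$beats, f_s = cfg$f_s,
                      init = attr(ss, "final_state"))
    truth_outputs <- list(
      LVEDV = max(ss$V_lv), RVEDV = max(ss$V_rv),
      P_lv_max = max(ss$P_lv), P_rv_max = max(ss$P_rv),
      MAP = waveform_mean(ss$P_ao), MPAP = waveform_mean(ss$P_pa),
      SV = stroke_volume(ss$V_lv, ss$V_rv),
      GEDV = max(ss$V_lv) + max(ss$V_rv))
    wn <- add_measurement_noise(w, cfg$noise_sd, cfg$rv_factor)
    sp <- extract_setpoints(wn)
    out$waveforms[[lbl]] <- wn
    out$setpoints[[lbl]] <- sp
    out$truth[[lbl]] <- list(params = p, outputs = truth_outputs)
  }
  out$subject <- subject
  out$config <- cfg
  out$seed <- seed
  class(out) <- "cvs_dataset"
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' @export
print.cvs_dataset <- function(x, ...) {
  cat(sprintf("<cvs_dataset> subject seed %d: %d timepoints (%d failed)\n",
              x$subject$seed, length(x$waveforms), length(x$failed)))
  invisible(x)
}
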