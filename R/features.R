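#' Time-weighted mean of a one-beat trace
#'
#' For a uniformly sampled periodic beat the trapezoidal time average over
#' exactly one period (closing the beat with its first sample) reduces to
#' the arithmetic mean of the samples; for an explicit, possibly
#' non-uniform time base the open trapezoidal rule is used.
#'
#' @param x Numeric samples spanning one beat.
#' @param t Optional sample times in seconds (non-uniform case).
#' @return Mean value, same units as `x`.
#' @export
#' @examples
#' waveform_mean(rep(80, 100))  # 80
waveform_mean <- function(x, t = NULL) {
  if (length(x) < 2) stop("need at least 2 samples spanning one beat")
  if (is.null(t)) return(mean(x))
  dt <- diff(t)
  sum((head(x, -1) + tail(x, -1)) / 2 * dt) / (t[length(t)] - t[1])
}

#' Amplitude (pulse) of a one-beat trace
#'
#' @param x Numeric samples spanning one beat.
#' @return `max(x) - min(x)`.
#' @export
waveform_amplitude <- function(x) {
  if (length(x) < 1) stop("empty trace")
  max(x) - min(x)
}

#' Maximum ascending gradient of a one-beat trace
#'
#' The trace is smoothed with a 5-point quadratic (Savitzky-Golay)
#' window, differentiated by central differences, and the maximum of the
#' derivative returned.  On a physiological pressure beat this is the
#' steepest systolic upstroke.
#'
#' @param x Numeric samples over one beat.
#' @param f_s Sampling frequency in Hz.
#' @param smooth_window Odd window length of the quadratic smoother.
#' @return Maximum derivative in units of `x` per second.
#' @export
#' @examples
#' max_ascending_gradient(seq(0, 100, length.out = 101), f_s = 200)  # 200
max_ascending_gradient <- function(x, f_s, smooth_window = 5) {
  n <- length(x)
  if (n <= smooth_window) stop("trace shorter than smoothing window")
  xs <- signal::sgolayfilt(x, p = 2, n = smooth_window)
  d <- numeric(n)
  d[2:(n - 1)] <- (xs[3:n] - xs[1:(n - 2)]) * f_s / 2
  d[1] <- (xs[2] - xs[1]) * f_s
  d[n] <- (xs[n] - xs[n - 1]) * f_s
  max(d)
}

#' Stroke volume from the two ventricular volume traces
#'
#' The average of the amplitudes of the left and right ventricular volume
#' waveforms over one beat.  Averaging the two sides guards against a
#' systematic underestimation of either conductance-derived volume: in a
#' closed circulation the steady-state stroke volumes of the two
#' ventricles must agree.
#'
#' @param v_lv,v_rv One-beat ventricular volume traces in mL.
#' @return Stroke volume in mL.
#' @export
stroke_volume <- function(v_lv, v_rv) {
  (waveform_amplitude(v_lv) + waveform_amplitude(v_rv)) / 2
}

#' Global end diastolic volume
#'
#' @param lvedv,rvedv Left/right ventricular end diastolic volumes, mL.
#' @return `lvedv + rvedv` in mL.
#' @export
#' @examples
#' gedv(97.7, 93.3)
gedv <- function(lvedv, rvedv) {
  if (any(c(lvedv, rvedv) < 0)) stop("end diastolic volumes must be >= 0")
  lvedv + rvedv
}

#' End diastolic volume from a one-beat volume trace
#'
#' With monotone filling followed by ejection the end of diastole is the
#' volume maximum of the beat (reached at atrioventricular valve
#' closure).  When an activation-onset marker is supplied the maximum is
#' taken over the half beat preceding the onset (with a small slack past
#' it, since the inflow valve closes just after activation begins),
#' wrapping periodically.
#'
#' @param v One-beat volume trace in mL.
#' @param t Sample times in s (defaults to a uniform grid over the beat).
#' @param onset Optional activation-onset time in s, within the beat.
#' @return End diastolic volume in mL.
#' @export
end_diastolic_volume <- function(v, t = NULL, onset = NULL) {
  n <- length(v)
  if (n < 2) stop("empty trace")
  if (is.null(onset)) return(max(v))
  if (is.null(t)) t <- seq(0, 1, length.out = n + 1)[1:n] * n / n
  period <- t[n] + (t[2] - t[1])
  if (onset < 0 || onset >= period) stop("onset marker outside trace")
  lo <- onset - period / 2
  hi <- onset + 0.08 * period
  keep <- ((t - lo) %% period) <= ((hi - lo) %% period)
  max(v[keep])
}

#' Estimate a driver function from an arterial pressure beat
#'
#' Reconstructs a normalised time-varying elastance from the shape of the
#' arterial pressure waveform.  The ejection window is delimited by the
#' steepest upstroke (maximum ascending gradient) and steepest fall
#' (minimum gradient, the dicrotic landmark); within it the activation
#' follows the normalised pressure, and outside it decays as a Gaussian
#' whose width is set so the activation crosses the valve-closure
#' threshold at the upstroke landmark.  The result has maximum exactly 1
#' and minimum at least 0.  If no usable landmarks are found (e.g. a flat
#' trace) a parametric driver at the same period is returned with
#' attribute `fallback = TRUE`.
#'
#' @param p One-beat arterial pressure trace in mmHg.
#' @param period Beat period in s.
#' @param f_s Sampling frequency in Hz.
#' @param delta Activation threshold associated with valve closure.
#' @param n_grid Number of samples of the returned curve.
#' @return A `cvs_driver` (sampled), or a parametric fallback flagged via
#'   `attr(, "fallback")`.
#' @export
estimate_driver <- function(p, period, f_s, delta = 0.05, n_grid = 200) {
  n <- length(p)
  fallback <- function() {
    d <- cvs_driver(period)
    attr(d, "fallback") <- TRUE
    d
  }
  if (n < 11 || waveform_amplitude(p) < 1e-6 * max(abs(p), 1)) {
    return(fallback())
  }
  ps <- signal::sgolayfilt(p, p = 3, n = min(11, n - (1 - n %% 2)))
  d <- c(ps[2] - ps[1], (ps[3:n] - ps[1:(n - 2)]) / 2,
         ps[n] - ps[n - 1]) * f_s
  i_up <- which.max(d)
  i_dn <- which.min(d)
  i_pk <- which.max(ps)
  t <- (seq_len(n) - 1) / f_s
  if (!(i_up < i_pk && i_pk <= i_dn) || d[i_up] <= 0) return(fallback())
  t_peak <- t[i_pk]
  half <- t_peak - t[i_up]
  if (half <= 0.02 * period) return(fallback())
  W <- log(1 / delta) / half^2
  grid <- seq(0, period, length.out = n_grid + 1)[1:n_grid]
  gauss <- exp(-W * pmin(abs(grid - t_peak),
                         period - abs(grid - t_peak))^2)
  y <- gauss
  # inside the ejection window follow the normalised pressure shape
  win <- grid >= t[i_up] & grid <= t[i_dn]
  if (any(win)) {
    pw <- approx(t, ps, xout = grid[win], rule = 2)$y
    lo <- min(pw)
    hi <- max(pw)
    if (hi > lo) {
      edge <- exp(-W * (t[i_up] - t_peak)^2)
      y[win] <- edge + (1 - edge) * (pw - lo) / (hi - lo)
    }
  }
  sampled_driver(y, period)
}

#' Valve closure time from a driver function
#'
#' Activation onset is read off as the first time within the beat at
#' which the driver exceeds the fraction `delta` of its maximum; for an
#' atrioventricular valve this onset marks valve closure.  For the
#' parametric Gaussian driver this is the closed form
#' `t_peak - sqrt(log(1/delta) / W)` (wrapped into the beat).
#'
#' @param driver A `cvs_driver`.
#' @param delta Threshold as a fraction of the driver maximum, in (0, 1).
#' @return Closure time in seconds relative to beat onset, in
#'   `[0, period)`.
#' @export
valve_closure_time <- function(driver, delta = 0.05) {
  stopifnot(inherits(driver, "cvs_driver"))
  if (delta <= 0 || delta >= 1)
    stop("delta must lie strictly between 0 and 1")
  if (driver$type == "gauss") {
    return((driver$t_peak - sqrt(log(1 / delta) / driver$width)) %%
             driver$period)
  }
  y <- driver$values
  n <- length(y)
  grid <- (seq_len(n) - 1) / n * driver$period
  i_pk <- which.max(y)
  # walk back from the peak to the last sample below threshold
  idx <- c(seq(i_pk, 1), seq(n, i_pk + 1))
  below <- idx[which(y[idx] < delta)[1]]
  if (is.na(below)) stop("driver never falls below the threshold")
  nxt <- if (below == n) 1L else below + 1L
  t0 <- grid[below]
  frac <- (delta - y[below]) / (y[nxt] - y[below])
  (t0 + frac * driver$period / n) %% driver$period
}

# Valve closure from the cessation of inflow.  Because the clamped diode
# flow is identically zero past closure, linear interpolation on the flow
# itself quantises the crossing to the sample grid; when the gating
# pressure difference `dp` (upstream minus ventricular pressure) is
# available its zero crossing locates closure at sub-sample resolution.
# `last = TRUE` returns the final closure in the window (used when the
# window spans more than one beat).
closure_time_from_flow <- function(q, t, dp = NULL, last = FALSE) {
  n <- length(q)
  trans <- which(q[-n] > 1e-9 & q[-1] <= 1e-9)
  if (!length(trans)) return(NA_real_)
  i <- if (last) trans[length(trans)] else trans[1]
  frac <- q[i] / (q[i] - q[i + 1])
  if (!is.null(dp) && length(dp) == n && is.finite(dp[i]) &&
      is.finite(dp[i + 1]) && dp[i] > 0 && dp[i + 1] < 0)
    frac <- dp[i] / (dp[i] - dp[i + 1])
  t[i] + frac * (t[i + 1] - t[i])
}

# Savitzky-Golay smoothing with the window expressed in samples at the
# 200 Hz reference rate and rescaled to the actual sampling rate, so
# the smoothed bandwidth (and its small peak-flattening bias) is the
# same at any rate.
smooth_trace <- function(x, window, f_s = 200) {
  n <- length(x)
  w <- round(window * f_s / 200)
  w <- w + (1 - w %% 2)                  # odd
  w <- max(5, w)
  w <- min(w, n - (1 - n %% 2))
  if (w < 5 || window < 5) return(x)
  signal::sgolayfilt(x, p = 3, n = w)
}

#' Extract convergence set points from a beat-level waveform set
#'
#' Reduces a waveform record to the minimal measurement set driving
#' parameter identification: global end diastolic volume, stroke volume,
#' mean and pulse pressures and maximum ascending gradients of the aortic
#' and pulmonary artery pressures, the mitral and tricuspid valve closure
#' times, and the beat period.  The last complete beat of the record is
#' used.
#'
#' Valve closure times are read from the mitral/tricuspid flow traces
#' (cessation of inflow) when those are present in the record; otherwise
#' they are estimated from driver functions reconstructed from the
#' arterial pressure shapes ([estimate_driver()]).
#'
#' @param w A `cvs_waveform` tibble (simulated or read from CSV).
#' @param period Beat period in s; defaults to the driver period stored
#'   with a simulated waveform, or the full record length.
#' @param smooth_window Savitzky-Golay window applied to each measured
#'   trace before feature extraction, in samples at the 200 Hz reference
#'   rate (rescaled to the record's actual rate); below 5 disables
#'   smoothing.
#' @param delta Activation threshold for driver-based closure times.
#' @return A one-row `cvs_setpoints` tibble with columns `GEDV`, `SV`,
#'   `MAP`, `MPAP`, `PP_ao`, `PP_pa`, `dPao_max`, `dPpa_max`, `t_mt`,
#'   `t_tc`, `T`, `heart_rate`.
#' @export
extract_setpoints <- function(w, period = NULL, smooth_window = 7,
                              delta = 0.05) {
  f_s <- attr(w, "f_s")
  if (is.null(f_s)) stop("waveform has no sampling-frequency attribute")
  if (is.null(period)) period <- attr(w, "period")
  if (is.null(period)) period <- nrow(w) / f_s
  per_beat <- round(period * f_s)
  n_beats <- floor(nrow(w) / (period * f_s) + 1e-9)
  if (n_beats < 1) stop("no complete beat in record")
  # align the analysis window to the true beat grid (an integer number
  # of samples per beat drifts relative to the period over a long
  # record)
  start <- round((n_beats - 1) * period * f_s)
  idx <- pmin(start + seq_len(per_beat), nrow(w))
  b <- w[idx, ]
  t <- b$t - b$t[1]

  sm <- function(x) smooth_trace(x, smooth_window, f_s)
  P_ao <- sm(b$P_ao)
  P_pa <- sm(b$P_pa)
  have_vol <- all(c("V_lv", "V_rv") %in% names(b)) &&
    !all(is.na(b$V_lv)) && !all(is.na(b$V_rv))
  if (!have_vol) stop("waveform record lacks ventricular volume traces")
  V_lv <- sm(b$V_lv)
  V_rv <- sm(b$V_rv)

  lvedv <- end_diastolic_volume(V_lv)
  rvedv <- end_diastolic_volume(V_rv)
  sv <- stroke_volume(V_lv, V_rv)

  have_flow <- all(c("Q_mt", "Q_tc") %in% names(b)) &&
    !all(is.na(b$Q_mt)) && !all(is.na(b$Q_tc))
  if (have_flow) {
    # closure sits within milliseconds of beat onset and can fall just
    # outside a one-beat window; detect it on a two-beat window (when
    # available) and report it modulo the period from the beat onset
    start2 <- max(0, round((n_beats - 2) * period * f_s))
    idx2 <- pmin(start2 + seq_len(min(2 * per_beat, nrow(w))), nrow(w))
    b2 <- w[idx2, ]
    t2 <- b2$t - b$t[1]          # zero at the analysed beat's onset
    dp_mt <- if (all(c("P_pu", "P_lv") %in% names(b2)))
      b2$P_pu - sm(b2$P_lv) else NULL
    dp_tc <- if (all(c("P_vc", "P_rv") %in% names(b2)))
      b2$P_vc - sm(b2$P_rv) else NULL
    t_mt <- closure_time_from_flow(b2$Q_mt, t2, dp_mt, last = TRUE)
    t_tc <- closure_time_from_flow(b2$Q_tc, t2, dp_tc, last = TRUE)
    if (!is.na(t_mt)) t_mt <- t_mt %% period
    if (!is.na(t_tc)) t_tc <- t_tc %% period
  } else {
    t_mt <- t_tc <- NA_real_
  }
  if (is.na(t_mt))
    t_mt <- valve_closure_time(estimate_driver(P_ao, period, f_s, delta),
                               delta)
  if (is.na(t_tc))
    t_tc <- valve_closure_time(estimate_driver(P_pa, period, f_s, delta),
                               delta)

  sp <- tibble(
    GEDV = gedv(lvedv, rvedv), SV = sv,
    MAP = waveform_mean(P_ao), MPAP = waveform_mean(P_pa),
    PP_ao = waveform_amplitude(P_ao), PP_pa = waveform_amplitude(P_pa),
    dPao_max = max_ascending_gradient(P_ao, f_s),
    dPpa_max = max_ascending_gradient(P_pa, f_s),
    t_mt = t_mt, t_tc = t_tc,
    T = period, heart_rate = 60 / period
  )
  class(sp) <- c("cvs_setpoints", class(sp))
  sp
}

#' Validate a set-point record
#'
#' Checks the internal consistency of a convergence set-point record:
#' positive volumes with `GEDV > SV`, positive pulse pressures, and valve
#' closure times within the beat.
#'
#' @param sp A `cvs_setpoints` row (or anything coercible to a list with
#'   the same names).
#' @return `sp`, invisibly; errors describe the violated condition.
#' @export
validate_setpoints <- function(sp) {
  s <- as.list(sp)
  if (!(s$SV > 0)) stop("stroke volume must be positive")
  if (!(s$GEDV > s$SV))
    stop("inconsistent set points: GEDV must exceed SV")
  if (!(s$PP_ao > 0 && s$PP_pa > 0))
    stop("pulse pressures must be positive")
  if (!(s$MAP > 0 && s$MPAP > 0)) stop("mean pressures must be positive")
  for (tm in c("t_mt", "t_tc"))
    if (is.na(s[[tm]]) || s[[tm]] < 0 || s[[tm]] >= s$T)
      stop(tm, " must lie within [0, T)")
  invisible(sp)
}
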