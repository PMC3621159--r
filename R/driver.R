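#' Cardiac driver function (normalised time-varying elastance)
#'
#' The driver function is the normalised activation of a ventricle over
#' one heartbeat: a periodic curve in \[0, 1\] that reaches 1 at a single
#' peak per period and blends the end-systolic and end-diastolic
#' pressure-volume relationships of the active chambers.
#'
#' The parametric form is a normalised Gaussian pulse
#' `exp(-W * (t mod T - t_peak)^2)` with its peak at `peak_frac * T`.  The
#' default width keeps the pulse shape fixed in normalised time,
#' `W = 45 / T^2` (equivalently `W = 80` s^-2 at a period of 0.75 s), so
#' that systole occupies the same fraction of the beat at any heart rate.
#'
#' @param period Heartbeat period T in seconds (> 0).
#' @param peak_frac Peak position as a fraction of the period.
#' @param width Gaussian width parameter W in 1/s^2; default `45 / period^2`.
#' @return An object of class `cvs_driver`.
#' @seealso [sampled_driver()] for a curve estimated from data,
#'   [driver_value()] to evaluate it.
#' @export
#' @examples
#' d <- cvs_driver(0.75)
#' driver_value(d, 0.3 * 0.75)  # 1 at the peak
cvs_driver <- function(period, peak_frac = 0.3, width = NULL) {
  if (!is.numeric(period) || length(period) != 1 || !is.finite(period) ||
      period <= 0)
    stop("invalid driver: period must be a positive number")
  if (is.null(width)) width <- 45 / period^2
  if (width <= 0) stop("invalid driver: width must be positive")
  structure(list(type = "gauss", period = period,
                 t_peak = peak_frac * period, width = width),
            class = "cvs_driver")
}

#' Sampled driver function
#'
#' Wraps a sampled activation curve (values on a uniform grid over one
#' period) as a driver.  The curve is rescaled so its maximum is exactly 1
#' and clipped below at 0; evaluation interpolates linearly and
#' periodically.
#'
#' @param values Numeric vector of activation samples over `[0, period)`.
#' @param period Heartbeat period in seconds.
#' @return An object of class `cvs_driver`.
#' @export
sampled_driver <- function(values, period) {
  if (!is.numeric(period) || period <= 0)
    stop("invalid driver: period must be positive")
  if (length(values) < 4 || !all(is.finite(values)))
    stop("invalid driver: need at least 4 finite samples")
  v <- pmax(values, 0)
  if (max(v) <= 0) stop("invalid driver: curve is identically zero")
  v <- v / max(v)
  structure(list(type = "sampled", period = period, values = v),
            class = "cvs_driver")
}

#' Evaluate a driver function
#'
#' @param driver A `cvs_driver`.
#' @param t Time(s) in seconds; evaluation is periodic in the driver
#'   period.
#' @return Activation value(s) in \[0, 1\].
#' @export
#' @examples
#' d <- cvs_driver(0.75, peak_frac = 0.4, width = 80)
#' driver_value(d, 0.2)  # exp(-80 * 0.01)
driver_value <- function(driver, t) {
  stopifnot(inherits(driver, "cvs_driver"))
  if (!all(is.finite(t))) stop("t must be finite")
  vapply(t, function(ti) cpp_driver_value(unclass(driver), ti), numeric(1))
}

#' @export
print.cvs_driver <- function(x, ...) {
  if (x$type == "gauss") {
    cat(sprintf("<cvs_driver> Gaussian pulse: T=%.4g s, peak at %.4g s, W=%.4g /s^2\n",
                x$period, x$t_peak, x$width))
  } else {
    cat(sprintf("<cvs_driver> sampled curve: T=%.4g s, %d samples\n",
                x$period, length(x$values)))
  }
  invisible(x)
}

#' Driver peak time
#'
#' Time within the beat at which the activation attains its maximum.
#' @param driver A `cvs_driver`.
#' @return Peak time in seconds, in `[0, period)`.
#' @export
driver_peak_time <- function(driver) {
  stopifnot(inherits(driver, "cvs_driver"))
  if (driver$type == "gauss") return(driver$t_peak %% driver$period)
  grid <- seq(0, driver$period, length.out = length(driver$values) + 1)
  grid[which.max(driver$values)]
}
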