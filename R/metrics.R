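#' Bland-Altman bias and precision
#'
#' Agreement between a modelled and a measured series: differences are
#' taken as `modelled - measured`; bias is their mean and precision twice
#' their sample (n-1) standard deviation.
#'
#' @param measured,modelled Equal-length numeric series.
#' @return Named list with `bias` and `precision` in the input units.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 22, 32))  # bias 2, precision 0
bland_altman <- function(measured, modelled) {
  if (length(measured) != length(modelled)) stop("length mismatch")
  if (length(measured) < 2) stop("need at least 2 pairs")
  d <- modelled - measured
  list(bias = mean(d), precision = 2 * sd(d))
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between two series.
#'
#' @param x,y Numeric series of equal length (>= 3), `x` with nonzero
#'   variance.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate series: zero variance")
  cor(x, y)^2
}

#' Absolute percentage-error summary
#'
#' Elementwise absolute percentage errors
#' `100 * |modelled - measured| / |measured|`, summarised by their median
#' and 5th/95th percentiles (linear interpolation between order
#' statistics).
#'
#' @param measured,modelled Equal-length series; `measured` nonzero.
#' @return Named list with `median`, `p5`, `p95` (percent).
#' @export
percentage_error_stats <- function(measured, modelled) {
  if (length(measured) != length(modelled)) stop("length mismatch")
  if (any(measured == 0)) stop("measured values must be nonzero")
  e <- 100 * abs(modelled - measured) / abs(measured)
  q <- quantile(e, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  list(median = q[2], p5 = q[1], p95 = q[3])
}

#' Right ventricular-arterial coupling
#'
#' The ratio of right ventricular end-systolic elastance to the
#' (pulmonary) arterial afterload elastance, `E_es_rvf / E_a`; see
#' [afterload_metric()] for `E_a`.
#'
#' @param E_es_rvf Right ventricular end-systolic elastance, mmHg/mL.
#' @param E_a Arterial elastance, mmHg/mL (> 0).
#' @return Dimensionless coupling ratio.
#' @export
#' @examples
#' rvac(0.8, afterload_metric(0.03, 0.4, 0.5))
rvac <- function(E_es_rvf, E_a) {
  if (any(E_a <= 0)) stop("E_a must be positive")
  E_es_rvf / E_a
}

#' Agreement report for one or more quantities
#'
#' Tidy wrapper combining [bland_altman()], [r_squared()] and
#' [percentage_error_stats()] per quantity.
#'
#' @param data A data frame with columns `quantity`, `measured`,
#'   `modelled` (long form, one row per paired observation).
#' @return A tibble with one row per quantity: `bias`, `precision`,
#'   `r_squared`, `pct_err_median`, `pct_err_p5`, `pct_err_p95`, `n`.
#' @export
agreement_report <- function(data) {
  stopifnot(all(c("quantity", "measured", "modelled") %in% names(data)))
  data |>
    dplyr::group_by(.data$quantity) |>
    dplyr::group_modify(function(d, key) {
      ba <- bland_altman(d$measured, d$modelled)
      pe <- percentage_error_stats(d$measured, d$modelled)
      r2 <- tryCatch(r_squared(d$measured, d$modelled),
                     error = function(e) NA_real_)
      tibble(bias = ba$bias, precision = ba$precision, r_squared = r2,
             pct_err_median = pe$median, pct_err_p5 = pe$p5,
             pct_err_p95 = pe$p95, n = nrow(d))
    }) |>
    dplyr::ungroup()
}
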