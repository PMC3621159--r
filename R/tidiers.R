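identifiable_params <- c("E_es_lvf", "E_es_rvf", "R_mt", "R_av", "R_tc",
                         "R_pv", "R_sys", "R_pul", "E_ao", "E_pa",
                         "E_vc", "E_pu")

#' Tidy an identified model
#'
#' @param x A `cvs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per identifiable parameter: `term`,
#'   `estimate`.
#' @export
tidy.cvs_fit <- function(x, ...) {
  tibble(term = identifiable_params,
         estimate = vapply(identifiable_params,
                           function(n) x$params[[n]], numeric(1)))
}

#' One-row summary of an identified model
#'
#' @param x A `cvs_fit`.
#' @param ... Unused.
#' @return A tibble with convergence diagnostics and the main modelled
#'   outputs.
#' @export
glance.cvs_fit <- function(x, ...) {
  tibble(converged = x$converged, iterations = x$iterations,
         worst_residual_pct = max(x$residuals$residual_pct, na.rm = TRUE),
         LVEDV = x$outputs$LVEDV, RVEDV = x$outputs$RVEDV,
         P_lv_max = x$outputs$P_lv_max, P_rv_max = x$outputs$P_rv_max,
         E_a = afterload_metric(x$params$R_pv, x$params$R_pul,
                                x$params$driL$period),
         RVAC = rvac(x$params$E_es_rvf,
                     afterload_metric(x$params$R_pv, x$params$R_pul,
                                      x$params$driL$period)))
}

#' Tidy a subject series
#'
#' @param x A `cvs_series`.
#' @param pass `"refit"` (valve-averaged, default) or `"fit"` (first
#'   pass).
#' @param ... Unused.
#' @return Long tibble: `timepoint`, `term`, `estimate`, `converged`.
#' @export
tidy.cvs_series <- function(x, pass = c("refit", "fit"), ...) {
  pass <- match.arg(pass)
  fits <- if (pass == "refit") x$refits else x$fits
  purrr::imap_dfr(fits, function(f, lbl) {
    dplyr::mutate(tidy(f), timepoint = lbl, converged = f$converged,
                  .before = 1)
  })
}

#' @rdname tidy.cvs_series
#' @export
glance.cvs_series <- function(x, ...) {
  tibble(n_timepoints = length(x$fits),
         n_converged = sum(x$converged),
         R_mt = x$valve_resistances[["R_mt"]],
         R_av = x$valve_resistances[["R_av"]],
         R_tc = x$valve_resistances[["R_tc"]],
         R_pv = x$valve_resistances[["R_pv"]])
}

#' Parameter-trajectory plot for a subject series
#'
#' @param object A `cvs_series`.
#' @param terms Parameters to display.
#' @param ... Unused.
#' @return A ggplot object: one facet per parameter over the timepoints.
#' @export
autoplot.cvs_series <- function(object,
                                terms = c("R_sys", "R_pul", "E_es_lvf",
                                          "E_es_rvf"), ...) {
  d <- tidy(object) |>
    dplyr::filter(.data$term %in% terms) |>
    dplyr::mutate(t_min = as.numeric(sub("^T", "", .data$timepoint)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_min, y = .data$estimate)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$converged)) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "identified value")
}

#' Bland-Altman plot
#'
#' @param data Long data frame with `quantity`, `measured`, `modelled`.
#' @return A ggplot object: difference against mean with bias and 2SD
#'   limits per quantity.
#' @export
plot_bland_altman <- function(data) {
  d <- data |>
    dplyr::mutate(avg = (.data$measured + .data$modelled) / 2,
                  diff = .data$modelled - .data$measured)
  lims <- d |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(bias = mean(.data$diff),
                     lo = mean(.data$diff) - 2 * sd(.data$diff),
                     hi = mean(.data$diff) + 2 * sd(.data$diff))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(data = lims,
                        ggplot2::aes(yintercept = .data$bias)) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$lo),
                        linetype = 2) +
    ggplot2::geom_hline(data = lims, ggplot2::aes(yintercept = .data$hi),
                        linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free") +
    ggplot2::labs(x = "mean of modelled and measured",
                  y = "modelled - measured")
}
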