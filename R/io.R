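#' Read a waveform CSV
#'
#' Loads a beat-level waveform record.  The file must have a header row
#' and at least the columns `t`, `P_ao`, `P_pa`; any further pressure,
#' volume or flow columns are carried along.  The time base must be
#' strictly increasing and uniform; the sampling frequency is inferred
#' from it.
#'
#' @param path CSV file path.
#' @param period Optional beat period in s, attached to the result for
#'   beat segmentation.
#' @return A `cvs_waveform` tibble with attributes `f_s` and `period`.
#' @export
read_waveforms <- function(path, period = NULL) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("t", "P_ao", "P_pa")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  dt <- diff(d$t)
  if (any(dt <= 0)) stop("non-monotone time base")
  if (diff(range(dt)) > 1e-6 * mean(dt))
    stop("non-uniform time base")
  w <- as_tibble(d)
  structure(w, class = c("cvs_waveform", class(w)), f_s = 1 / mean(dt),
            period = period, converged = NA, beats_run = NA)
}

#' Write a waveform record to CSV
#'
#' @param w A `cvs_waveform` tibble.
#' @param path Output path.
#' @param digits Significant digits retained.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(w, path, digits = 10) {
  d <- as.data.frame(w)
  d[] <- lapply(d, function(x) signif(x, digits))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a set-point record as flat JSON
#'
#' Set points are stored keyed by their standard symbols (`GEDV`, `SV`,
#' `MAP`, `MPAP`, `PP_ao`, `PP_pa`, `dPao_max`, `dPpa_max`, `t_mt`,
#' `t_tc`, `T`).
#'
#' @param sp A `cvs_setpoints` row.
#' @param path JSON file path.
#' @return `write_setpoints` returns `path` invisibly; `read_setpoints`
#'   a `cvs_setpoints` tibble.
#' @export
write_setpoints <- function(sp, path) {
  jsonlite::write_json(as.list(sp), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_setpoints
#' @export
read_setpoints <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- as_tibble(x)
  class(sp) <- c("cvs_setpoints", class(sp))
  sp
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), "relation_cache")]
  s <- paste(deparse(keep), collapse = "")
  # small rolling-polynomial digest; stable across sessions
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

fit_to_list <- function(fit) {
  list(parameters = setNames(
         lapply(identifiable_params, function(n) fit$params[[n]]),
         identifiable_params),
       P_pu = fit$venous_targets[["P_pu"]],
       P_vc = fit$venous_targets[["P_vc"]],
       heart_rate = fit$params$heart_rate,
       V_total = fit$params$V_total,
       converged = fit$converged,
       iterations = fit$iterations,
       outputs = fit$outputs,
       residuals_pct = setNames(as.list(fit$residuals$residual_pct),
                                fit$residuals$output))
}

#' Write an identified model (or subject series) to JSON
#'
#' Serialises parameter estimates keyed by their standard symbols,
#' together with residuals, convergence flags, iteration counts, the
#' configuration hash, and (for a series) the averaged valve-resistance
#' block.
#'
#' @param x A `cvs_fit` or `cvs_series`.
#' @param path Output JSON path.
#' @param cfg The [identification_config()] used (hashed into the file).
#' @param seed Optional seed recorded alongside.
#' @return `path`, invisibly.
#' @export
write_identified <- function(x, path, cfg = identification_config(),
                             seed = NULL) {
  body <- if (inherits(x, "cvs_series")) {
    list(kind = "series",
         valve_resistances = as.list(x$valve_resistances),
         timepoints = purrr::map(x$refits, fit_to_list),
         first_pass = purrr::map(x$fits, fit_to_list))
  } else {
    c(list(kind = "fit"), fit_to_list(x))
  }
  body$config_hash <- config_hash(cfg)
  body$seed <- seed
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read back an identified-model JSON
#'
#' @param path JSON path written by [write_identified()].
#' @return A nested list mirroring the file.
#' @export
read_identified <- function(path) jsonlite::read_json(path,
                                                      simplifyVector = TRUE)

write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lbl in names(ds$waveforms)) {
    write_waveforms(ds$waveforms[[lbl]],
                    file.path(dir, paste0("waveforms_", lbl, ".csv")))
    write_setpoints(ds$setpoints[[lbl]],
                    file.path(dir, paste0("setpoints_", lbl, ".json")))
  }
  truth <- purrr::map(ds$truth, function(tp) {
    list(parameters = setNames(
           lapply(identifiable_params, function(n) tp$params[[n]]),
           identifiable_params),
         heart_rate = tp$params$heart_rate,
         V_total = tp$params$V_total,
         outputs = tp$outputs)
  })
  jsonlite::write_json(list(subject_seed = ds$subject$seed,
                            noise_seed = ds$seed, failed = ds$failed,
                            timepoints = truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read or write a run configuration
#'
#' A run configuration couples the identification settings and the
#' septic-trajectory settings with the seed and sampling rate; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @param config A list with any of the fields `identification`
#'   (arguments of [identification_config()]), `sepsis` (arguments of
#'   [sepsis_config()]), `seed`, `f_s`.
#' @return `read_run_config` returns the parsed and validated list with
#'   `identification` and `sepsis` instantiated.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("identification", "sepsis", "seed", "f_s")
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  check_args <- function(given, fn, what) {
    ok <- names(formals(fn))
    bad <- setdiff(names(given), ok)
    if (length(bad))
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
    given
  }
  ident <- do.call(identification_config,
                   check_args(x$identification %||% list(),
                              identification_config, "identification"))
  seps <- do.call(sepsis_config,
                  check_args(x$sepsis %||% list(), sepsis_config, "sepsis"))
  list(identification = ident, sepsis = seps, seed = x$seed %||% 1,
       f_s = x$f_s %||% 200)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
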