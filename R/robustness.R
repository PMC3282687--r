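# Quasi-multiparameter sensitivity (QMPS) and cumulative-frequency
# comparison of robustness across competing models.

#' Normalized single-parameter sensitivity (forward difference)
#'
#' The relative change of a target function under a small relative
#' perturbation of one parameter:
#' \eqn{s_i = ((q(p_i (1+\Delta)) - q(p)) / q(p)) / \Delta}.
#' The forward (one-sided) difference at `delta = 0.001` is used throughout;
#' it matches the defining perturbation \eqn{p_i (1 + \Delta)}.
#'
#' @param target_fn Function taking a named parameter vector and returning a
#'   scalar (or `NA` when the target is undefined, e.g. oscillation lost).
#' @param params Named parameter vector with `target_fn(params)` finite and
#'   nonzero.
#' @param index Name or position of the perturbed parameter.
#' @param delta Relative perturbation, in (0, 0.01].
#' @return Signed dimensionless sensitivity, or `NA` if the perturbed target
#'   is undefined.
#' @export
single_param_sensitivity <- function(target_fn, params, index,
                                     delta = 0.001) {
  stopifnot(delta > 0, delta <= 0.01)
  q0 <- target_fn(params)
  if (!is.finite(q0) || q0 == 0)
    stop("target function must be finite and nonzero at the base parameters",
         call. = FALSE)
  pp <- params
  pp[index] <- pp[index] * (1 + delta)
  qp <- target_fn(pp)
  if (!is.finite(qp)) return(NA_real_)
  ((qp - q0) / q0) / delta
}

#' Quasi-multiparameter sensitivity of a target function
#'
#' QMPS is the square sum of the normalized single-parameter sensitivities
#' evaluated by finite differences at relative perturbation `delta`
#' (default 0.001; values below 0.01 give consistent results). It
#' approximates the multiparameter sensitivity (MPS), the analytic
#' \eqn{\Delta \to 0} limit. Lower QMPS means a more robust target.
#' `n + 1` target evaluations are needed for `n` parameters.
#'
#' @inheritParams single_param_sensitivity
#' @param param_names Parameters to perturb (default: all of `params`).
#'   Fixed parameters such as the Hill coefficient must be excluded by the
#'   caller when using a raw target function; the clock-specific wrappers do
#'   this automatically.
#' @return List with `qmps` (square sum; `NA` if any sensitivity is
#'   undefined), `sensitivities` (named vector) and `n_undefined`.
#' @examples
#' # multiplicatively linear target: each sensitivity is exactly 1
#' qmps(function(p) p[["a"]] * p[["b"]], c(a = 2, b = 3))$qmps  # 2
#' @export
qmps <- function(target_fn, params, delta = 0.001,
                 param_names = names(params)) {
  stopifnot(delta > 0, delta <= 0.01, length(param_names) >= 1)
  q0 <- target_fn(params)
  if (!is.finite(q0) || q0 == 0)
    stop("target function must be finite and nonzero at the base parameters",
         call. = FALSE)
  s <- vapply(param_names, function(nm) {
    pp <- params
    pp[nm] <- pp[nm] * (1 + delta)
    qp <- target_fn(pp)
    if (!is.finite(qp)) NA_real_ else ((qp - q0) / q0) / delta
  }, numeric(1))
  n_undef <- sum(is.na(s))
  list(qmps = if (n_undef) NA_real_ else sum(s^2),
       sensitivities = s, n_undefined = n_undef)
}

#' QMPS of period and amplitude for one clock parameter set
#'
#' Computes the quasi-multiparameter sensitivity of the oscillation period
#' and amplitude of the output component with respect to every searched
#' kinetic parameter (the fixed Hill coefficient is never perturbed). To cut
#' transient cost, perturbed (and baseline) measurements restart from the
#' final state of an unperturbed run and use a shorter window
#' (`restart_horizon` / `restart_transient`); feature extraction is
#' attractor-determined, so this matches the full-transient policy. Both
#' targets share the same perturbed simulations, so `n + 1` integrations
#' cover both. A perturbed system that loses sustained oscillation renders
#' the QMPS of that parameter set undefined (`NA`); such sets are excluded
#' and counted, never imputed.
#'
#' @param model A [clock_model()].
#' @param params Accepted (oscillating) parameter vector.
#' @param delta Relative perturbation (default 0.001).
#' @param restart_horizon,restart_transient Window (h) for the restarted
#'   measurements.
#' @param horizon,transient,dt,min_peaks,period_cv_max,amplitude_cv_max
#'   Simulation policy, as in [oscillation_features()].
#' @return List with `period` and `amplitude` (QMPS values or `NA`),
#'   `sensitivities` (2-row matrix) and `n_undefined`.
#' @export
clock_qmps <- function(model, params, delta = 0.001,
                       restart_horizon = 600, restart_transient = 300,
                       horizon = 1000, transient = 500, dt = 0.25,
                       min_peaks = 10, period_cv_max = 0.01,
                       amplitude_cv_max = 0.10) {
  stopifnot(inherits(model, "clock_model"))
  p <- validate_params(model$architecture, params)
  base <- integrate_clock(model, params = p, horizon = horizon, dt = dt,
                          transient = transient, record_from = transient)
  undef <- list(period = NA_real_, amplitude = NA_real_,
                sensitivities = NULL, n_undefined = NA_integer_)
  if (!base$ok) return(undef)
  y_end <- base$states[nrow(base$states), ]

  measure <- function(pp) {
    tr <- integrate_clock(model, params = pp, horizon = restart_horizon,
                          dt = dt, transient = restart_transient,
                          record_from = restart_transient, init = y_end)
    f <- oscillation_features(tr, model, min_peaks = min_peaks,
                              period_cv_max = period_cv_max,
                              amplitude_cv_max = amplitude_cv_max)
    if (!f$sustained) c(NA_real_, NA_real_) else c(f$period, f$amplitude)
  }

  q0 <- measure(p)
  if (any(!is.finite(q0))) return(undef)
  nm <- searched_parameters(model$architecture)
  sens <- vapply(nm, function(j) {
    pp <- p
    pp[j] <- pp[j] * (1 + delta)
    ((measure(pp) - q0) / q0) / delta
  }, numeric(2))
  rownames(sens) <- c("period", "amplitude")
  n_undef <- sum(is.na(sens[1, ]))
  list(period = if (n_undef) NA_real_ else sum(sens["period", ]^2),
       amplitude = if (n_undef) NA_real_ else sum(sens["amplitude", ]^2),
       sensitivities = sens, n_undefined = n_undef)
}

#' QMPS for every entry of a solution archive
#'
#' @param model A [clock_model()] matching the archive's architecture.
#' @param archive A `solution_archive` from [run_tps()].
#' @param ... Passed to [clock_qmps()].
#' @return Data frame with one row per archive entry: `qmps_period`,
#'   `qmps_amplitude`, `n_undefined`, `defined`.
#' @export
archive_qmps <- function(model, archive, ...) {
  stopifnot(inherits(archive, "solution_archive"),
            model$architecture == archive$architecture)
  res <- lapply(archive_parameters(archive), function(p)
    clock_qmps(model, p, ...))
  data.frame(
    qmps_period = vapply(res, `[[`, numeric(1), "period"),
    qmps_amplitude = vapply(res, `[[`, numeric(1), "amplitude"),
    n_undefined = vapply(res, `[[`, numeric(1), "n_undefined"),
    defined = vapply(res, function(r) is.finite(r$period), logical(1)))
}

#' Empirical cumulative frequency
#'
#' The fraction of observed values at or below `x`. With `x = NULL`, returns
#' the full non-decreasing, right-continuous step curve evaluated at the
#' sorted values (CF at the maximum is 1).
#'
#' @param values Non-empty finite numeric vector (NAs dropped).
#' @param x Optional evaluation point(s).
#' @return Fractions in \[0, 1\], or a data frame `x`/`cf` when `x = NULL`.
#' @export
cumulative_frequency <- function(values, x = NULL) {
  values <- values[is.finite(values)]
  stopifnot(length(values) >= 1)
  if (is.null(x)) {
    v <- sort(values)
    return(data.frame(x = v, cf = seq_along(v) / length(v)))
  }
  vapply(x, function(xx) mean(values <= xx), numeric(1))
}

#' Median as the 0.5 cumulative-frequency crossing
#'
#' The smallest observed value whose cumulative frequency reaches 0.5. A
#' lower median QMPS indicates a more robust model ensemble.
#'
#' @param values Non-empty finite numeric vector (NAs dropped).
#' @return The median value.
#' @export
cf_median <- function(values) {
  values <- sort(values[is.finite(values)])
  stopifnot(length(values) >= 1)
  values[ceiling(length(values) / 2)]
}

#' Compare robustness across competing model ensembles
#'
#' Summarizes per-model QMPS value lists into cumulative-frequency curves
#' and medians, retaining the count of excluded entries (parameter sets
#' whose QMPS was undefined because a perturbation destroyed the
#' oscillation). A model whose CF curve lies above another's — or, when
#' curves cross, whose median is lower — is the more robust oscillator.
#'
#' @param qmps_values Named list of numeric QMPS vectors (NAs = excluded
#'   entries).
#' @return A `robustness_comparison`: list with `medians`, `n`, `n_excluded`
#'   and `curves` (per-model CF data frames).
#' @export
compare_models <- function(qmps_values) {
  stopifnot(is.list(qmps_values), length(qmps_values) >= 1,
            !is.null(names(qmps_values)))
  defined <- lapply(qmps_values, function(v) v[is.finite(v)])
  stopifnot(all(vapply(defined, length, integer(1)) >= 1))
  structure(list(
    medians = vapply(defined, cf_median, numeric(1)),
    n = vapply(defined, length, integer(1)),
    n_excluded = vapply(qmps_values, function(v) sum(!is.finite(v)),
                        integer(1)),
    curves = lapply(defined, cumulative_frequency)),
    class = "robustness_comparison")
}

#' @export
print.robustness_comparison <- function(x, ...) {
  cat("<robustness_comparison>\n")
  for (nm in names(x$medians))
    cat(sprintf("  %-24s median QMPS %10.4g  (n = %d, excluded = %d)\n",
                nm, x$medians[[nm]], x$n[[nm]], x$n_excluded[[nm]]))
  invisible(x)
}
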