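# Light-dark forcing, entrainment classification, and the zeta-delta
# entrainment probability map.

#' Light-dark schedule
#'
#' A square-wave light-dark cycle of forcing period `zeta` with equal light
#' and dark phases (duty cycle fixed at 0.5) and lights-on at t = 0. During
#' the light phase the maximum degradation rate of cytoplasmic clock protein
#' X (parameter D2) — and, in the semi-dual and dual models, of the
#' cytoplasmic X:Y complex (D5) — is multiplied by `1 + delta`; during the
#' dark phase it takes its free-running value. The neutral point is
#' `delta = 0` (light has no effect); `delta` must exceed -1 so rates stay
#' positive.
#'
#' @param zeta Forcing period (h).
#' @param delta Light-induced relative increase of the degradation vmax
#'   (dimensionless).
#' @return A `light_schedule` object.
#' @export
light_schedule <- function(zeta, delta) {
  stopifnot(zeta > 0)
  if (delta <= -1)
    stop("delta <= -1 would make the light-phase degradation rate non-positive",
         call. = FALSE)
  structure(list(zeta = zeta, delta = delta, duty = 0.5),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule: zeta = %g h, delta = %g, duty 0.5>\n",
              x$zeta, x$delta))
  invisible(x)
}

#' Attach a light-dark schedule to a clock model
#'
#' Returns a time-dependent model whose light-modulated degradation rates
#' follow the square-wave schedule. [integrate_clock()] integrates it
#' phase-by-phase with event-aligned restarts, so the discontinuous
#' switching is never stepped over.
#'
#' @param model A [clock_model()].
#' @param schedule A [light_schedule()].
#' @return The model with the schedule attached (`model$schedule`).
#' @export
forced_model <- function(model, schedule) {
  stopifnot(inherits(model, "clock_model"),
            inherits(schedule, "light_schedule"))
  model$schedule <- schedule
  model
}

#' Classify entrainment of one parameter set to a light-dark cycle
#'
#' Integrates the forced model for `cycles` forcing periods, discards the
#' first `discard`, and classifies the remainder: successful entrainment
#' (`En = 1`) requires the period and amplitude of the output oscillation to
#' be constant (cycle-to-cycle deviations below 1% and 10% respectively) and
#' the oscillation period to equal the forcing period within 1%. Integration
#' failure or a damped response yields `En = 0`.
#'
#' @param model A [clock_model()].
#' @param params Parameter set (typically an accepted free-running
#'   oscillator).
#' @param schedule A [light_schedule()].
#' @param cycles,discard Total and discarded forcing cycles.
#' @param dt Output grid spacing (h).
#' @param min_peaks Minimum number of peaks in the classified window.
#' @param period_tol,amplitude_tol Constancy tolerances (cycle-to-cycle CV).
#' @param lock_tol Maximum relative deviation of the oscillation period from
#'   the forcing period.
#' @return Logical `En`, with the measured forced period (h) as attribute
#'   `"period"` (`NA` when undefined).
#' @export
is_entrained <- function(model, params, schedule, cycles = 80, discard = 40,
                         dt = 0.25, min_peaks = 10, period_tol = 0.01,
                         amplitude_tol = 0.10, lock_tol = 0.01) {
  stopifnot(inherits(schedule, "light_schedule"))
  horizon <- cycles * schedule$zeta
  transient <- discard * schedule$zeta
  traj <- integrate_clock(model, params = params, horizon = horizon,
                          dt = dt, transient = transient,
                          record_from = transient, schedule = schedule)
  f <- oscillation_features(traj, model, min_peaks = min_peaks,
                            period_cv_max = period_tol,
                            amplitude_cv_max = amplitude_tol)
  en <- f$sustained &&
    abs(f$period - schedule$zeta) / schedule$zeta < lock_tol
  structure(isTRUE(en), period = f$period)
}

#' Entrainment probability map over a zeta-delta grid
#'
#' For every archived parameter set and every grid point, classifies
#' entrainment with [is_entrained()]; the probability at a grid point is the
#' exact fraction of parameter sets that entrain there (so probability times
#' the archive size is always an integer). Per-set booleans are retained for
#' audit.
#'
#' @param model A [clock_model()] matching the archive.
#' @param archive A `solution_archive` from [run_tps()].
#' @param zeta_grid Forcing periods (h); default 33 points over 16-32 h.
#' @param delta_grid Light factors; default 33 log-spaced points over a
#'   decade (0.1-1).
#' @param ... Passed to [is_entrained()].
#' @return An `entrainment_map`: list with `zeta`, `delta`, `probability`
#'   (matrix zeta x delta), `en` (array sets x zeta x delta) and `N`.
#' @export
entrainment_map <- function(model, archive,
                            zeta_grid = seq(16, 32, length.out = 33),
                            delta_grid = 10^seq(-1, 0, length.out = 33),
                            ...) {
  stopifnot(inherits(archive, "solution_archive"),
            model$architecture == archive$architecture,
            length(archive$entries) >= 1)
  psets <- archive_parameters(archive)
  N <- length(psets)
  en <- array(FALSE, dim = c(N, length(zeta_grid), length(delta_grid)),
              dimnames = list(NULL, NULL, NULL))
  for (j in seq_along(zeta_grid)) {
    for (k in seq_along(delta_grid)) {
      sched <- light_schedule(zeta_grid[j], delta_grid[k])
      en[, j, k] <- vapply(psets, function(p)
        as.logical(is_entrained(model, p, sched, ...)), logical(1))
    }
  }
  probability <- apply(en, c(2, 3), mean)
  dimnames(probability) <- list(zeta = signif(zeta_grid, 6),
                                delta = signif(delta_grid, 6))
  structure(list(architecture = model$architecture, zeta = zeta_grid,
                 delta = delta_grid, probability = probability,
                 en = en, N = N),
            class = "entrainment_map")
}

#' @export
print.entrainment_map <- function(x, ...) {
  cat(sprintf(
    "<entrainment_map: %s feedback, %d sets, %d x %d grid, mean P = %.3f>\n",
    x$architecture, x$N, length(x$zeta), length(x$delta),
    mean(x$probability)))
  invisible(x)
}

#' @export
as.data.frame.entrainment_map <- function(x, ...) {
  g <- expand.grid(zeta = x$zeta, delta = x$delta)
  g$probability <- as.vector(x$probability)
  g$n_entrained <- as.vector(apply(x$en, c(2, 3), sum))
  g$N <- x$N
  g
}

#' Total entrained area of a map
#'
#' The mean entrainment probability over the grid — a scalar summary of how
#' widely an ensemble entrains across forcing periods and light intensities.
#'
#' @param map An `entrainment_map`.
#' @return Mean probability in \[0, 1\].
#' @export
entrained_area <- function(map) {
  stopifnot(inherits(map, "entrainment_map"))
  mean(map$probability)
}
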