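# Integration, transient handling, oscillation feature extraction, and the
# loop-balance statistic gamma.

#' Integrate a clock model
#'
#' Solves the model ODEs with a stiff-capable variable-step integrator
#' (`lsoda`) on a fixed dense output grid. Integration failures
#' (stiffness/blow-up) are flagged on the returned object rather than raised,
#' so parameter searches can continue; [oscillation_features()] treats a
#' failed trajectory as non-oscillatory.
#'
#' @param model A [clock_model()].
#' @param params Optional parameter override (named vector).
#' @param horizon Integration end time (h). The default 1000 h with a 500 h
#'   transient leaves about 20 circadian cycles for feature extraction.
#' @param dt Output grid spacing (h).
#' @param transient Time (h) before which output is discarded when computing
#'   features.
#' @param init Initial concentration, recycled over species (nM). All-0.1 nM
#'   by default; the post-transient attractor, not the start, determines the
#'   reported features.
#' @param record_from Earliest time to record (h); defaults to 0. Searches
#'   record only the post-transient window to save memory.
#' @param schedule Optional [light_schedule()] for light-dark forcing;
#'   `NULL` means constant darkness.
#' @param engine `"C"` (compiled, default) or `"R"` (the rate-law composition
#'   in [clock_derivatives()]; slow, used for cross-checking).
#' @param rtol,atol Relative / absolute integrator tolerances.
#' @param maxsteps `lsoda` step budget per output interval.
#' @return A `clock_trajectory`: list with `times`, `states` (matrix, one
#'   column per species), `architecture`, `post_transient_start` (index),
#'   `transient`, `schedule`, and `ok` (FALSE if integration failed).
#' @export
integrate_clock <- function(model, params = NULL, horizon = 1000, dt = 0.25,
                            transient = 500, init = 0.1, record_from = 0,
                            schedule = NULL, engine = c("C", "R"),
                            rtol = 1e-7, atol = 1e-9, maxsteps = 10000) {
  stopifnot(inherits(model, "clock_model"))
  engine <- match.arg(engine)
  if (is.null(schedule) && !is.null(model$schedule)) schedule <- model$schedule
  p <- if (is.null(params)) model$params
       else validate_params(model$architecture, params)
  m <- model$n_equations
  y0 <- rep_len(init, m)
  stopifnot(all(y0 >= 0))
  # coarse checkpoints through any unrecorded transient keep lsoda's
  # per-output-interval step budget meaningful
  times <- unique(c(seq(0, max(0, record_from), by = 5),
                    seq(max(0, record_from), horizon, by = dt)))

  delta <- 0
  events <- NULL
  light0 <- 0
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "light_schedule"))
    delta <- schedule$delta
    light0 <- 1                       # lights on at t = 0
    sw <- seq(schedule$zeta / 2, horizon, by = schedule$zeta / 2)
    events <- list(data = data.frame(
      var = "light", time = sw,
      value = rep_len(c(0, 1), length(sw)), method = "rep"))
  }

  # integrator diagnostics for failing (stiff/blow-up) candidates are
  # reported via the trajectory's ok flag, not the console
  quiet <- function(expr) {
    con <- file(nullfile(), open = "w")
    sink(con)
    on.exit({ sink(); close(con) })
    suppressWarnings(expr)
  }

  y <- c(setNames(y0, model$species), light = light0)
  out <- if (engine == "C") {
    quiet(try(deSolve::ode(
      y = y, times = times, func = model$arch$derivfunc,
      parms = c(p, delta = delta), dllname = "clockloops",
      initfunc = model$arch$initfunc, method = "lsoda",
      rtol = rtol, atol = atol, maxsteps = maxsteps, events = events),
      silent = TRUE))
  } else {
    rhs <- function(t, y, parms) {
      lf <- 1 + delta * y[m + 1]
      list(c(clock_derivatives(model, y[seq_len(m)], params = p,
                               light_factor = lf), 0))
    }
    quiet(try(deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                           method = "lsoda", rtol = rtol, atol = atol,
                           maxsteps = maxsteps, events = events),
              silent = TRUE))
  }

  ok <- !inherits(out, "try-error")
  if (ok) {
    out <- as.matrix(out)
    ok <- nrow(out) >= length(times) && all(is.finite(out))
  }
  if (!ok) {
    return(structure(list(times = numeric(0),
                          states = matrix(numeric(0), 0, m,
                                          dimnames = list(NULL, model$species)),
                          architecture = model$architecture,
                          post_transient_start = NA_integer_,
                          transient = transient, schedule = schedule,
                          ok = FALSE),
                     class = "clock_trajectory"))
  }
  tt <- out[, 1]
  structure(list(times = tt,
                 states = out[, model$species, drop = FALSE],
                 light = out[, "light"],
                 architecture = model$architecture,
                 post_transient_start = match(TRUE, tt >= transient),
                 transient = transient, schedule = schedule, ok = TRUE),
            class = "clock_trajectory")
}

#' @export
print.clock_trajectory <- function(x, ...) {
  if (!x$ok) {
    cat("<clock_trajectory: integration failed>\n")
  } else {
    cat(sprintf("<clock_trajectory: %s, %d samples over [%g, %g] h>\n",
                x$architecture, length(x$times), min(x$times), max(x$times)))
  }
  invisible(x)
}

#' @export
as.data.frame.clock_trajectory <- function(x, ...) {
  if (!x$ok) return(data.frame(time = numeric(0), species = character(0),
                               value = numeric(0)))
  data.frame(time = rep(x$times, ncol(x$states)),
             species = rep(colnames(x$states), each = length(x$times)),
             value = as.vector(x$states))
}

#' Clock output signal of a trajectory
#'
#' The output component is nuclear X for the single model, the nuclear X:Y
#' complex for the semi-dual and dual models, and total nuclear protein
#' (X_nuc + Y_nuc) for the redundant model.
#'
#' @param model A [clock_model()].
#' @param traj A `clock_trajectory`.
#' @return Numeric vector of output concentrations (nM) on the trajectory
#'   grid.
#' @export
output_signal <- function(model, traj) {
  stopifnot(inherits(traj, "clock_trajectory"))
  rowSums(traj$states[, model$output, drop = FALSE])
}

# Local maxima of a sampled signal with an absolute prominence filter and
# three-point parabolic refinement of peak times/heights. Removes numerical
# ripple without biasing the period.
peak_times <- function(t, x, prominence = 1e-3) {
  n <- length(x)
  empty <- list(time = numeric(0), value = numeric(0), index = integer(0))
  if (n < 5) return(empty)
  d <- diff(x)
  cand <- which(d[-(n - 1)] > 0 & d[-1] <= 0) + 1L
  if (!length(cand)) return(empty)
  keep <- vapply(seq_along(cand), function(j) {
    i <- cand[j]
    lo <- if (j == 1) 1L else cand[j - 1]
    hi <- if (j == length(cand)) n else cand[j + 1]
    (x[i] - max(min(x[lo:i]), min(x[i:hi]))) > prominence
  }, logical(1))
  cand <- cand[keep]
  if (!length(cand)) return(empty)
  tp <- t[cand]; vp <- x[cand]
  inner <- cand > 1L & cand < n
  i <- cand[inner]
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  safe <- abs(denom) > .Machine$double.eps
  off <- ifelse(safe, 0.5 * (x[i - 1] - x[i + 1]) / denom, 0)
  off <- pmax(-0.5, pmin(0.5, off))
  dt <- t[i + 1] - t[i]
  tp[inner] <- t[i] + off * dt
  vp[inner] <- x[i] - 0.25 * (x[i - 1] - x[i + 1]) * off
  list(time = tp, value = vp, index = cand)
}

#' Extract oscillation features from a trajectory
#'
#' Operates on the post-transient window of the output signal. The period is
#' the mean peak-to-peak interval (peak times refined by three-point
#' parabolic interpolation); the amplitude is max - min of the output over
#' the window. An oscillation counts as sustained when at least `min_peaks`
#' peaks are detected and the cycle-to-cycle coefficients of variation of
#' period and amplitude fall below `period_cv_max` and `amplitude_cv_max`
#' (these thresholds deliberately mirror the entrainment constancy criteria).
#' Damped, constant, or failed trajectories yield `sustained = FALSE` with
#' `period` and `amplitude` reported as `NA`.
#'
#' @param traj A `clock_trajectory`.
#' @param model The [clock_model()] it came from (defines the output
#'   component).
#' @param min_peaks Minimum number of detected peaks.
#' @param period_cv_max,amplitude_cv_max Cycle-to-cycle relative-variation
#'   thresholds (defaults 1% and 10%).
#' @param prominence Absolute peak prominence threshold (nM).
#' @return An `oscillation_features` list: `period` (h), `amplitude` (nM),
#'   `sustained`, `n_peaks`, `period_cv`, `amplitude_cv`, `mean_levels`
#'   (per-species post-transient means, nM).
#' @export
oscillation_features <- function(traj, model, min_peaks = 10,
                                 period_cv_max = 0.01,
                                 amplitude_cv_max = 0.10,
                                 prominence = 1e-3) {
  stopifnot(inherits(traj, "clock_trajectory"))
  not_sustained <- function(n_peaks = 0L, mean_levels = NULL)
    structure(list(period = NA_real_, amplitude = NA_real_, sustained = FALSE,
                   n_peaks = n_peaks, period_cv = NA_real_,
                   amplitude_cv = NA_real_, mean_levels = mean_levels),
              class = "oscillation_features")
  if (!traj$ok || is.na(traj$post_transient_start)) return(not_sustained())

  w <- seq(traj$post_transient_start, length(traj$times))
  tt <- traj$times[w]
  sig <- output_signal(model, traj)[w]
  mean_levels <- colMeans(traj$states[w, , drop = FALSE])
  pk <- peak_times(tt, sig, prominence = prominence)
  n_peaks <- length(pk$time)
  if (n_peaks < max(2L, min_peaks))
    return(not_sustained(n_peaks, mean_levels))

  iv <- diff(pk$time)
  period <- mean(iv)
  period_cv <- sd(iv) / period
  # per-cycle amplitude: max - min between successive peaks
  amp_cycle <- vapply(seq_len(n_peaks - 1L), function(j) {
    seg <- sig[pk$index[j]:pk$index[j + 1]]
    max(pk$value[j:(j + 1)]) - min(seg)
  }, numeric(1))
  amplitude_cv <- sd(amp_cycle) / mean(amp_cycle)
  amplitude <- max(sig) - min(sig)
  sustained <- is.finite(period) && period > 0 && amplitude > 0 &&
    period_cv < period_cv_max && amplitude_cv < amplitude_cv_max
  structure(list(period = period, amplitude = amplitude,
                 sustained = sustained, n_peaks = n_peaks,
                 period_cv = period_cv, amplitude_cv = amplitude_cv,
                 mean_levels = mean_levels),
            class = "oscillation_features")
}

#' @export
print.oscillation_features <- function(x, ...) {
  if (x$sustained) {
    cat(sprintf("<oscillation: period %.3f h, amplitude %.3f nM, %d peaks>\n",
                x$period, x$amplitude, x$n_peaks))
  } else {
    cat(sprintf("<no sustained oscillation (%d peaks)>\n", x$n_peaks))
  }
  invisible(x)
}

#' Loop-balance statistic gamma
#'
#' Quantifies the balance of the X and Y feedback loops of the redundant
#' model as \eqn{\gamma = [X_{nuc}]_{mean} / ([X_{nuc}]_{mean} +
#' [Y_{nuc}]_{mean})} over the post-transient window. \eqn{\gamma = 0.5}
#' means both loops contribute equally; values near 0 (or 1) mean the Y (or
#' X) loop dominates. Under perfect kinetic symmetry (\eqn{\rho = 0}) gamma
#' is always exactly 0.5.
#'
#' @param traj A `clock_trajectory` of a redundant-architecture model.
#' @param model The corresponding [clock_model()].
#' @return Gamma in \[0, 1\], or `NA` if both nuclear means are zero or the
#'   architecture has no separate nuclear X and Y species.
#' @export
loop_balance <- function(traj, model) {
  stopifnot(inherits(traj, "clock_trajectory"))
  if (!all(c("X_nuc", "Y_nuc") %in% model$species)) return(NA_real_)
  if (!traj$ok || is.na(traj$post_transient_start)) return(NA_real_)
  w <- seq(traj$post_transient_start, length(traj$times))
  mx <- mean(traj$states[w, "X_nuc"])
  my <- mean(traj$states[w, "Y_nuc"])
  if (mx + my <= 0) return(NA_real_)
  mx / (mx + my)
}
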