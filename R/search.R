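# Two-phase search (TPS): log-uniform random sampling of kinetic parameter
# space seeding a genetic algorithm, harvesting every parameter set whose
# simulated oscillation satisfies the circadian fitness windows.

#' Search configuration for the two-phase search
#'
#' @param rho Kinetic-symmetry parameter for the dual and redundant models
#'   (ignored otherwise). `rho = 0` forces every Y-loop parameter equal to
#'   its X-loop counterpart; `rho >= 99` leaves the loops independent.
#' @param y_stratum Optional length-2 interval (nM) constraining the
#'   post-transient mean total Y protein (free + complexed) of the semi-dual
#'   model, e.g. `c(0, 10)`, `c(10, 200)`, `c(200, Inf)`.
#' @param fold Global multiplicative search range around the reference
#'   values (default 0.1-10 fold).
#' @param period_window Target period window (h), default 23-25 h.
#' @param amplitude_window Target amplitude window (nM), default 2-6 nM.
#' @param n_solutions Number of distinct accepted parameter sets to harvest.
#' @param random_trials Number of random-phase samples.
#' @param pop_size,max_generations,crossover_rate,mutation_rate,mutation_sd,elite,tournament
#'   Genetic-algorithm settings: BLX-0.5 blend crossover applied with
#'   probability `crossover_rate`, per-gene Gaussian mutation (sd
#'   `mutation_sd` in log10 units) with probability `mutation_rate`,
#'   tournament selection of size `tournament`, `elite` individuals carried
#'   over unchanged.
#' @param distinct_tol Two solutions are duplicates when the maximum absolute
#'   log10 parameter ratio is below this value.
#' @param seed Integer seed; fans out deterministically to the two phases.
#' @param horizon,transient,dt Simulation policy (h) for fitness evaluation.
#' @param min_peaks,period_cv_max,amplitude_cv_max Sustained-oscillation
#'   criteria passed to [oscillation_features()].
#' @param nonosc_penalty Base penalty tier for non-oscillatory candidates.
#' @return A `search_config` list.
#' @export
search_config <- function(rho = 99, y_stratum = NULL, fold = c(0.1, 10),
                          period_window = c(23, 25),
                          amplitude_window = c(2, 6),
                          n_solutions = 100, random_trials = 5000,
                          pop_size = 100, max_generations = 200,
                          crossover_rate = 0.9, mutation_rate = 0.1,
                          mutation_sd = 0.1, elite = 1, tournament = 2,
                          distinct_tol = 0.01, seed = 1,
                          horizon = 1000, transient = 500, dt = 0.25,
                          min_peaks = 10, period_cv_max = 0.01,
                          amplitude_cv_max = 0.10, nonosc_penalty = 100) {
  stopifnot(rho >= 0, fold[1] > 0, fold[2] >= fold[1],
            period_window[1] > 0, diff(period_window) >= 0,
            amplitude_window[1] > 0, diff(amplitude_window) >= 0,
            n_solutions >= 1, random_trials >= 1, pop_size >= 2)
  if (!is.null(y_stratum))
    stopifnot(length(y_stratum) == 2, y_stratum[1] >= 0,
              y_stratum[2] > y_stratum[1])
  structure(as.list(environment()), class = "search_config")
}

# ---- fitness ---------------------------------------------------------------

# relative distance of v below/above window w; 0 inside
.window_dist <- function(v, w) max(0, (w[1] - v) / w[1], (v - w[2]) / w[2])

#' Circadian fitness of a set of oscillation features
#'
#' Zero if and only if the oscillation is sustained, the period lies in the
#' target period window, the amplitude in the target amplitude window, and
#' (when configured) the mean total Y level in its stratum. Otherwise a
#' positive penalty that decreases as period/amplitude approach their
#' windows; non-oscillatory candidates receive a maximal penalty tier
#' (at least `nonosc_penalty`, shaped by the number of detected peaks so the
#' genetic algorithm can climb toward oscillation).
#'
#' @param features An [oscillation_features()] result (or `NULL`).
#' @param config A [search_config()].
#' @param total_y Mean total Y protein (nM) when a `y_stratum` is configured.
#' @return Non-negative fitness (0 = accepted).
#' @export
circadian_fitness <- function(features, config, total_y = NULL) {
  if (is.null(features) || !isTRUE(features$sustained))
    return(config$nonosc_penalty +
             (10 - min(if (is.null(features)) 0L else features$n_peaks, 10)))
  pen <- .window_dist(features$period, config$period_window) +
    .window_dist(features$amplitude, config$amplitude_window)
  if (!is.null(config$y_stratum)) {
    if (is.null(total_y) || total_y <= 0) return(config$nonosc_penalty)
    lo <- max(config$y_stratum[1], .Machine$double.xmin)
    pen <- pen + max(0, log10(lo / total_y),
                     log10(total_y / config$y_stratum[2]))
  }
  pen
}

# ---- internal search machinery (log10 parameter space) ---------------------

# search-space description: per-gene log10 bounds, loop pairing indices
.search_space <- function(model, config) {
  nm <- searched_parameters(model$architecture)
  b <- parameter_bounds(model$architecture, config$fold)[, nm, drop = FALSE]
  pairs <- model$arch$xy_pairs
  list(names = nm, lower = log10(b["lower", ]), upper = log10(b["upper", ]),
       x_idx = if (!is.null(pairs)) match(names(pairs), nm),
       y_idx = if (!is.null(pairs)) match(unname(pairs), nm),
       rho = config$rho)
}

# clamp to global bounds, then pull Y-loop genes into the rho-band of their
# X-loop counterparts
.repair <- function(g, sp) {
  g <- pmin(pmax(g, sp$lower), sp$upper)
  if (!is.null(sp$x_idx)) {
    lr <- log10(1 + sp$rho)
    x <- g[sp$x_idx]
    g[sp$y_idx] <- pmin(pmax(g[sp$y_idx],
                             pmax(sp$lower[sp$y_idx], x - lr)),
                        pmin(sp$upper[sp$y_idx], x + lr))
  }
  g
}

.sample_genome <- function(sp) {
  g <- runif(length(sp$lower), sp$lower, sp$upper)
  if (!is.null(sp$x_idx)) {
    lr <- log10(1 + sp$rho)
    x <- g[sp$x_idx]
    lo <- pmax(sp$lower[sp$y_idx], x - lr)
    hi <- pmin(sp$upper[sp$y_idx], x + lr)
    g[sp$y_idx] <- runif(length(lo), lo, hi)
  }
  g
}

.genome_to_params <- function(g, sp, model) {
  p <- model$params
  p[sp$names] <- 10^g
  p
}

# simulate one candidate and score it
.evaluate <- function(g, sp, model, config) {
  p <- .genome_to_params(g, sp, model)
  traj <- integrate_clock(model, params = p, horizon = config$horizon,
                          dt = config$dt, transient = config$transient,
                          record_from = config$transient)
  f <- oscillation_features(traj, model, min_peaks = config$min_peaks,
                            period_cv_max = config$period_cv_max,
                            amplitude_cv_max = config$amplitude_cv_max)
  total_y <- if (model$architecture == "semi_dual" &&
                 !is.null(f$mean_levels))
    sum(f$mean_levels[c("Y", "XY", "XY_nuc")]) else NULL
  gamma <- if (model$architecture == "redundant") loop_balance(traj, model)
           else NA_real_
  list(genome = g, params = p, features = f, total_y = total_y,
       gamma = gamma,
       fitness = circadian_fitness(f, config, total_y = total_y))
}

.is_distinct <- function(g, genomes, tol) {
  if (!length(genomes)) return(TRUE)
  all(vapply(genomes, function(o) max(abs(g - o)) >= tol, logical(1)))
}

.archive_entry <- function(ev, phase, generation) {
  list(params = ev$params, period = ev$features$period,
       amplitude = ev$features$amplitude,
       period_cv = ev$features$period_cv,
       amplitude_cv = ev$features$amplitude_cv,
       n_peaks = ev$features$n_peaks,
       mean_levels = ev$features$mean_levels,
       total_y = if (is.null(ev$total_y)) NA_real_ else ev$total_y,
       gamma = ev$gamma,
       phase = phase, generation = generation)
}

#' Random phase of the two-phase search
#'
#' Samples `random_trials` parameter sets log-uniformly within the global
#' bounds (Y-loop parameters within their rho-band, conditionally on the
#' sampled X-loop values), evaluates the circadian fitness of each, archives
#' any solutions found, and returns the best `pop_size` candidates as the
#' seed population for the genetic algorithm.
#'
#' @param model A [clock_model()].
#' @param config A [search_config()].
#' @return List with `population` (list of evaluated candidates, best
#'   first), `solutions` (fitness-0 archive entries), `genomes` (their log10
#'   coordinates) and `n_evaluated`.
#' @export
random_phase <- function(model, config) {
  sp <- .search_space(model, config)
  evs <- vector("list", config$random_trials)
  fit <- numeric(config$random_trials)
  for (k in seq_len(config$random_trials)) {
    evs[[k]] <- .evaluate(.sample_genome(sp), sp, model, config)
    fit[k] <- evs[[k]]$fitness
  }
  solutions <- list(); genomes <- list()
  for (k in which(fit == 0)) {
    if (length(solutions) >= config$n_solutions) break
    if (.is_distinct(evs[[k]]$genome, genomes, config$distinct_tol)) {
      solutions[[length(solutions) + 1L]] <-
        .archive_entry(evs[[k]], "random", 0L)
      genomes[[length(genomes) + 1L]] <- evs[[k]]$genome
    }
  }
  ord <- order(fit)[seq_len(min(config$pop_size, length(fit)))]
  list(population = evs[ord], solutions = solutions, genomes = genomes,
       n_evaluated = config$random_trials)
}

#' Genetic-algorithm phase of the two-phase search
#'
#' Evolves the seed population in log10 parameter space under the same
#' bounds and symmetry constraints. Every individual reaching fitness 0 is
#' archived (subject to the distinctness tolerance) and replaced by a fresh
#' random sample to keep exploring, until `n_solutions` distinct solutions
#' are collected or `max_generations` is reached.
#'
#' @param pool Result of [random_phase()].
#' @param model A [clock_model()].
#' @param config A [search_config()].
#' @return A `solution_archive` (see [run_tps()]); a warning is issued if
#'   fewer than `n_solutions` solutions were found.
#' @export
ga_phase <- function(pool, model, config) {
  if (!length(pool$population))
    stop("random phase returned an empty candidate pool", call. = FALSE)
  sp <- .search_space(model, config)
  solutions <- pool$solutions
  genomes <- pool$genomes
  n_eval <- pool$n_evaluated

  pop <- pool$population
  npop <- config$pop_size
  # pad undersized pools with fresh random candidates
  while (length(pop) < npop) {
    pop[[length(pop) + 1L]] <- .evaluate(.sample_genome(sp), sp, model, config)
    n_eval <- n_eval + 1L
  }

  gen <- 0L
  while (length(solutions) < config$n_solutions &&
         gen < config$max_generations) {
    gen <- gen + 1L
    fit <- vapply(pop, `[[`, numeric(1), "fitness")

    # harvest and re-seed solutions
    for (k in which(fit == 0)) {
      if (length(solutions) < config$n_solutions &&
          .is_distinct(pop[[k]]$genome, genomes, config$distinct_tol)) {
        solutions[[length(solutions) + 1L]] <-
          .archive_entry(pop[[k]], "ga", gen)
        genomes[[length(genomes) + 1L]] <- pop[[k]]$genome
      }
      pop[[k]] <- .evaluate(.sample_genome(sp), sp, model, config)
      n_eval <- n_eval + 1L
      fit[k] <- pop[[k]]$fitness
    }
    if (length(solutions) >= config$n_solutions) break

    # selection / crossover / mutation with elitism
    ord <- order(fit)
    newpop <- pop[ord[seq_len(min(config$elite, npop))]]
    tourn <- function() {
      i <- sample.int(npop, config$tournament)
      pop[[i[which.min(fit[i])]]]$genome
    }
    while (length(newpop) < npop) {
      g1 <- tourn(); g2 <- tourn()
      if (runif(1) < config$crossover_rate) {    # BLX-0.5 blend
        lo <- pmin(g1, g2); hi <- pmax(g1, g2); d <- hi - lo
        g1 <- runif(length(g1), lo - 0.5 * d, hi + 0.5 * d)
      }
      mut <- runif(length(g1)) < config$mutation_rate
      g1[mut] <- g1[mut] + rnorm(sum(mut), 0, config$mutation_sd)
      newpop[[length(newpop) + 1L]] <-
        .evaluate(.repair(g1, sp), sp, model, config)
      n_eval <- n_eval + 1L
    }
    pop <- newpop
  }

  if (length(solutions) < config$n_solutions)
    warning(sprintf(
      "two-phase search collected %d of %d requested solutions (%d generations)",
      length(solutions), config$n_solutions, gen), call. = FALSE)
  structure(list(architecture = model$architecture, config = config,
                 entries = solutions, seed = config$seed,
                 n_evaluated = n_eval, generations = gen),
            class = "solution_archive")
}

#' Run the two-phase search
#'
#' Composition of [random_phase()] and [ga_phase()]: a seeded log-uniform
#' random search whose best candidates seed a genetic algorithm that
#' harvests parameter sets producing the target circadian oscillation
#' (sustained, period and amplitude within the configured windows, plus any
#' Y-level or kinetic-symmetry constraint). Deterministic given
#' `config$seed`.
#'
#' @param model A [clock_model()].
#' @param config A [search_config()].
#' @return A `solution_archive`: list with `architecture`, `config`,
#'   `entries` (each holding the accepted parameter vector, its oscillation
#'   features, total-Y level and gamma where defined, and search
#'   provenance), `seed`, `n_evaluated` and `generations`.
#' @export
run_tps <- function(model, config = search_config()) {
  stopifnot(inherits(model, "clock_model"), inherits(config, "search_config"))
  seeds <- derive_seeds(config$seed, c("random_phase", "ga_phase"))
  set.seed(seeds[["random_phase"]])
  pool <- random_phase(model, config)
  set.seed(seeds[["ga_phase"]])
  ga_phase(pool, model, config)
}

#' @export
print.solution_archive <- function(x, ...) {
  cat(sprintf("<solution_archive: %s feedback, %d entries (seed %d)>\n",
              x$architecture, length(x$entries), x$seed))
  if (length(x$entries)) {
    per <- vapply(x$entries, `[[`, numeric(1), "period")
    amp <- vapply(x$entries, `[[`, numeric(1), "amplitude")
    cat(sprintf("  period %.2f-%.2f h, amplitude %.2f-%.2f nM\n",
                min(per), max(per), min(amp), max(amp)))
  }
  invisible(x)
}

#' @export
length.solution_archive <- function(x) length(x$entries)

#' @export
as.data.frame.solution_archive <- function(x, ...) {
  if (!length(x$entries)) return(data.frame())
  pm <- do.call(rbind, lapply(x$entries, function(e) e$params))
  cbind(data.frame(
    period = vapply(x$entries, `[[`, numeric(1), "period"),
    amplitude = vapply(x$entries, `[[`, numeric(1), "amplitude"),
    gamma = vapply(x$entries, `[[`, numeric(1), "gamma"),
    total_y = vapply(x$entries, `[[`, numeric(1), "total_y"),
    phase = vapply(x$entries, `[[`, character(1), "phase"),
    generation = vapply(x$entries, `[[`, integer(1), "generation")),
    as.data.frame(pm))
}

#' Extract the accepted parameter sets of an archive
#'
#' @param archive A `solution_archive`.
#' @return List of named parameter vectors.
#' @export
archive_parameters <- function(archive) {
  stopifnot(inherits(archive, "solution_archive"))
  lapply(archive$entries, `[[`, "params")
}
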