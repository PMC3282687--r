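# Shared small solution archives, built once per test session and memoised
# in an environment (plus the on-disk fixture cache used by
# fixture_oscillator). Sizes are kept small: module tests only need a
# handful of accepted sets.

.test_cache <- new.env(parent = emptyenv())

test_archive <- function(architecture, rho = 99, y_stratum = NULL,
                         n = 8, seed = 101, random_trials = 800,
                         pop_size = 50, max_generations = 60) {
  key <- paste(architecture, rho,
               paste(y_stratum, collapse = "-"), n, seed, sep = "_")
  if (!is.null(.test_cache[[key]])) return(.test_cache[[key]])
  cfg <- search_config(rho = rho, y_stratum = y_stratum, n_solutions = n,
                       random_trials = random_trials, pop_size = pop_size,
                       max_generations = max_generations, seed = seed)
  arc <- suppressWarnings(run_tps(clock_model(architecture), cfg))
  .test_cache[[key]] <- arc
  arc
}

# Study ensembles for the replication tests (n = 60 accepted sets per
# condition, one fixed seed for all conditions), memoised so the
# robustness, balance and entrainment checks share them.
study_archive <- function(architecture, rho = 99, y_stratum = NULL) {
  test_archive(architecture, rho = rho, y_stratum = y_stratum,
               n = 60, seed = 11, random_trials = 2000,
               pop_size = 100, max_generations = 150)
}

study_qmps <- function(architecture, rho = 99, y_stratum = NULL) {
  key <- paste("qmps", architecture, rho,
               paste(y_stratum, collapse = "-"), sep = "_")
  if (!is.null(.test_cache[[key]])) return(.test_cache[[key]])
  q <- archive_qmps(clock_model(architecture),
                    study_archive(architecture, rho, y_stratum))
  .test_cache[[key]] <- q
  q
}

# one known-good oscillating parameter set (cached on disk)
test_params <- function(architecture = "single", seed = 1, rho = 99) {
  fixture_oscillator(architecture, seed = seed, rho = rho)$params
}

# hand-built trajectory around an analytic output signal, for feature tests
synthetic_trajectory <- function(signal_fn, architecture = "single",
                                 t = seq(500, 1000, by = 0.25)) {
  m <- clock_model(architecture)
  states <- matrix(0.5, nrow = length(t), ncol = m$n_equations,
                   dimnames = list(NULL, m$species))
  states[, m$output[1]] <- signal_fn(t)
  if (length(m$output) > 1) states[, m$output[-1]] <- 0
  structure(list(times = t, states = states,
                 architecture = architecture,
                 post_transient_start = 1L, transient = t[1],
                 schedule = NULL, ok = TRUE),
            class = "clock_trajectory")
}
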