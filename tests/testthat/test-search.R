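osc_features <- function(period, amplitude)
  structure(list(period = period, amplitude = amplitude, sustained = TRUE,
                 n_peaks = 20L, period_cv = 0.001, amplitude_cv = 0.01,
                 mean_levels = NULL),
            class = "oscillation_features")

test_that("fitness is zero exactly on the target windows", {
  cfg <- search_config()
  expect_equal(circadian_fitness(osc_features(24, 4), cfg), 0)
  expect_equal(circadian_fitness(osc_features(23, 2), cfg), 0)
  expect_equal(circadian_fitness(osc_features(25, 6), cfg), 0)
  expect_gt(circadian_fitness(osc_features(25.01, 4), cfg), 0)
  expect_gt(circadian_fitness(osc_features(24, 6.1), cfg), 0)
  # penalties shrink as the window approaches
  expect_lt(circadian_fitness(osc_features(26, 4), cfg),
            circadian_fitness(osc_features(30, 4), cfg))
  expect_lt(circadian_fitness(osc_features(24, 7), cfg),
            circadian_fitness(osc_features(24, 9), cfg))
  # non-oscillatory tier dominates every oscillatory penalty
  dead <- structure(list(period = NA, amplitude = NA, sustained = FALSE,
                         n_peaks = 3L, period_cv = NA, amplitude_cv = NA,
                         mean_levels = NULL), class = "oscillation_features")
  expect_gte(circadian_fitness(dead, cfg), cfg$nonosc_penalty)
  expect_gt(circadian_fitness(dead, cfg),
            circadian_fitness(osc_features(60, 40), cfg))
})

test_that("the Y-level stratum enters the fitness when configured", {
  cfg <- search_config(y_stratum = c(200, Inf))
  expect_equal(circadian_fitness(osc_features(24, 4), cfg, total_y = 300), 0)
  expect_gt(circadian_fitness(osc_features(24, 4), cfg, total_y = 50), 0)
  expect_lt(circadian_fitness(osc_features(24, 4), cfg, total_y = 150),
            circadian_fitness(osc_features(24, 4), cfg, total_y = 15))
})

test_that("random-phase sampling respects bounds and symmetry", {
  m <- clock_model("dual")
  for (rho in c(0, 0.5)) {
    cfg <- search_config(rho = rho, random_trials = 25, pop_size = 10,
                         n_solutions = 5, seed = 42)
    set.seed(1)
    pool <- random_phase(m, cfg)
    b <- parameter_bounds("dual")
    pairs <- loop_pairs("dual")
    for (cand in pool$population) {
      p <- cand$params
      nm <- searched_parameters("dual")
      expect_true(all(p[nm] >= b["lower", nm] - 1e-12))
      expect_true(all(p[nm] <= b["upper", nm] + 1e-12))
      for (x in names(pairs)) {
        yb <- y_loop_bounds(p[[x]], rho, b[, x])
        expect_true(p[[pairs[[x]]]] >= yb[1] * (1 - 1e-12) &&
                    p[[pairs[[x]]]] <= yb[2] * (1 + 1e-12))
        if (rho == 0) expect_equal(p[[pairs[[x]]]], p[[x]])
      }
    }
  }
})

test_that("the two-phase search is reproducible and windows-closed", {
  arc <- test_archive("single", n = 6)
  expect_gte(length(arc), 1)
  arc2 <- suppressWarnings(run_tps(clock_model("single"), arc$config))
  expect_identical(lapply(arc$entries, `[[`, "params"),
                   lapply(arc2$entries, `[[`, "params"))
  # a different seed explores differently but satisfies the same windows
  cfg3 <- arc$config
  cfg3$seed <- 202
  arc3 <- suppressWarnings(run_tps(clock_model("single"), cfg3))
  expect_false(identical(lapply(arc$entries, `[[`, "params"),
                         lapply(arc3$entries, `[[`, "params")))
  for (a in list(arc, arc3)) {
    per <- vapply(a$entries, `[[`, numeric(1), "period")
    amp <- vapply(a$entries, `[[`, numeric(1), "amplitude")
    expect_true(all(per >= 23 & per <= 25))
    expect_true(all(amp >= 2 & amp <= 6))
  }
})

test_that("archived entries re-simulate to the same oscillation", {
  arc <- test_archive("single", n = 6)
  m <- clock_model("single")
  for (e in arc$entries[seq_len(min(3, length(arc)))]) {
    f <- oscillation_features(integrate_clock(m, e$params,
                                              record_from = 500), m)
    expect_true(f$sustained)
    expect_equal(f$period, e$period, tolerance = 1e-6)
    expect_equal(f$amplitude, e$amplitude, tolerance = 1e-6)
  }
  expect_true(validate_archive(arc, k = 2))
})

test_that("archived solutions are pairwise distinct in log space", {
  arc <- test_archive("single", n = 6)
  nm <- searched_parameters("single")
  lg <- t(vapply(arc$entries, function(e) log10(e$params[nm]),
                 numeric(length(nm))))
  n <- nrow(lg)
  for (i in seq_len(n - 1))
    for (j in seq((i + 1), n))
      expect_gte(max(abs(lg[i, ] - lg[j, ])), arc$config$distinct_tol)
})

test_that("a pool already holding enough solutions skips evolution", {
  arc <- test_archive("single", n = 6)
  m <- clock_model("single")
  cfg <- arc$config
  cfg$n_solutions <- length(arc)
  nm <- searched_parameters("single")
  pool <- list(
    population = list(list(genome = log10(arc$entries[[1]]$params[nm]),
                           params = arc$entries[[1]]$params, fitness = 0)),
    solutions = arc$entries,
    genomes = lapply(arc$entries, function(e) log10(e$params[nm])),
    n_evaluated = 0L)
  out <- ga_phase(pool, m, cfg)
  expect_equal(out$generations, 0L)
  expect_equal(length(out), length(arc))
})

test_that("an unreachable target yields a partial archive with a warning", {
  cfg <- search_config(n_solutions = 50, random_trials = 20, pop_size = 8,
                       max_generations = 2, seed = 9)
  expect_warning(arc <- run_tps(clock_model("single"), cfg),
                 "collected")
  expect_lt(length(arc), 50)
})

test_that("dual rho=0 archives are perfectly loop-symmetric", {
  arc <- test_archive("dual", rho = 0, n = 5)
  pairs <- loop_pairs("dual")
  for (e in arc$entries)
    expect_equal(unname(e$params[unname(pairs)]),
                 unname(e$params[names(pairs)]))
})

test_that("semi-dual strata constrain the simulated total Y", {
  arc <- test_archive("semi_dual", y_stratum = c(200, Inf), n = 5)
  ty <- vapply(arc$entries, `[[`, numeric(1), "total_y")
  expect_true(all(ty > 200))
  # stored total_y is the post-transient mean of Y + XY + XY_nuc
  m <- clock_model("semi_dual")
  e <- arc$entries[[1]]
  f <- oscillation_features(integrate_clock(m, e$params, record_from = 500), m)
  expect_equal(sum(f$mean_levels[c("Y", "XY", "XY_nuc")]), e$total_y,
               tolerance = 1e-6)
})
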