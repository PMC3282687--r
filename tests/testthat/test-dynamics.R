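test_that("features of a pure sinusoid are recovered exactly", {
  traj <- synthetic_trajectory(function(t) 3 + 2 * sin(2 * pi * t / 24),
                               t = seq(500, 980, by = 0.25))  # 20 full cycles
  f <- oscillation_features(traj, clock_model("single"))
  expect_true(f$sustained)
  expect_equal(f$period, 24, tolerance = 1e-4)
  expect_equal(f$amplitude, 4, tolerance = 1e-6)
  expect_equal(unname(f$mean_levels["X_nuc"]), 3, tolerance = 1e-3)
})

test_that("damped and constant signals are not sustained", {
  damped <- synthetic_trajectory(function(t)
    3 + 2 * exp(-(t - 500) / 120) * sin(2 * pi * t / 24))
  f <- oscillation_features(damped, clock_model("single"))
  expect_false(f$sustained)

  const <- synthetic_trajectory(function(t) rep(3, length(t)))
  f2 <- oscillation_features(const, clock_model("single"))
  expect_false(f2$sustained)
  expect_equal(f2$n_peaks, 0L)
  expect_true(is.na(f2$period) && is.na(f2$amplitude))
})

test_that("too few cycles also fail the sustained criterion", {
  # real 24 h oscillation but only ~4 cycles in the window
  traj <- synthetic_trajectory(function(t) 3 + 2 * sin(2 * pi * t / 24),
                               t = seq(500, 600, by = 0.25))
  f <- oscillation_features(traj, clock_model("single"))
  expect_false(f$sustained)
  expect_lt(f$n_peaks, 10)
})

test_that("an (almost) silent gene yields an absorbing zero state", {
  p <- reference_parameters("single")
  p[c("S1", "S2")] <- 1e-12
  traj <- integrate_clock(clock_model("single"), p, horizon = 200,
                          transient = 0, init = 0)
  expect_true(traj$ok)
  expect_lt(max(traj$states), 1e-8)
})

test_that("integration is deterministic and engine-consistent", {
  p <- test_params("single")
  m <- clock_model("single")
  t1 <- integrate_clock(m, p, horizon = 300, transient = 0)
  t2 <- integrate_clock(m, p, horizon = 300, transient = 0)
  expect_identical(t1$states, t2$states)
  tR <- integrate_clock(m, p, horizon = 300, transient = 0, engine = "R")
  expect_lt(max(abs(t1$states - tR$states)), 1e-4)
})

test_that("period is stable under grid refinement and longer transients", {
  p <- test_params("single")
  m <- clock_model("single")
  f1 <- oscillation_features(integrate_clock(m, p), m)
  f2 <- oscillation_features(
    integrate_clock(m, p, dt = 0.125), m)
  expect_true(f1$sustained && f2$sustained)
  expect_lt(abs(f1$period - f2$period) / f1$period, 0.001)
  # doubling the discarded transient leaves features unchanged
  f3 <- oscillation_features(
    integrate_clock(m, p, horizon = 1500, transient = 1000), m)
  expect_lt(abs(f1$period - f3$period) / f1$period,
            max(f1$period_cv, 1e-3))
  expect_lt(abs(f1$amplitude - f3$amplitude) / f1$amplitude, 0.05)
})

test_that("failed integrations are flagged, not raised", {
  p <- reference_parameters("single")
  p["S1"] <- 1e6       # provoke integrator failure / blow-up handling
  p["D1"] <- 1e-12
  traj <- integrate_clock(clock_model("single"), p, horizon = 1000,
                          maxsteps = 10)
  f <- oscillation_features(traj, clock_model("single"))
  expect_false(f$sustained)
})

test_that("loop balance is the normalized nuclear-X share", {
  t <- seq(500, 979.75, by = 0.25)  # exactly 20 cycles: means are exact
  m <- clock_model("redundant")
  make <- function(mx, my) {
    st <- matrix(0.5, length(t), 6, dimnames = list(NULL, m$species))
    st[, "X_nuc"] <- mx + 0.5 * sin(2 * pi * t / 24)
    st[, "Y_nuc"] <- my + 0.5 * cos(2 * pi * t / 24)
    structure(list(times = t, states = st, architecture = "redundant",
                   post_transient_start = 1L, transient = 500,
                   schedule = NULL, ok = TRUE),
              class = "clock_trajectory")
  }
  expect_equal(loop_balance(make(2, 2), m), 0.5, tolerance = 1e-6)
  expect_equal(loop_balance(make(3, 1), m), 0.75, tolerance = 1e-6)
  # swapping the loops reflects gamma about one half
  tr <- make(3, 1)
  sw <- tr
  sw$states[, c("X_nuc", "Y_nuc")] <- tr$states[, c("Y_nuc", "X_nuc")]
  expect_equal(loop_balance(sw, m), 1 - loop_balance(tr, m),
               tolerance = 1e-12)
  expect_true(loop_balance(tr, m) >= 0 && loop_balance(tr, m) <= 1)
  # architectures without separate nuclear X and Y have no gamma
  expect_true(is.na(loop_balance(make(1, 1), clock_model("dual"))))
})

test_that("trajectories export to tidy long format", {
  p <- test_params("single")
  traj <- integrate_clock(clock_model("single"), p, horizon = 10, dt = 1,
                          transient = 0)
  df <- as.data.frame(traj)
  expect_named(df, c("time", "species", "value"))
  expect_equal(nrow(df), length(traj$times) * 3)
})
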