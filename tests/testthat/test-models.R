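test_that("reference parameters take the tabulated values", {
  for (a in architectures()) {
    p <- reference_parameters(a)
    lin <- clock_model(a)$arch$linear_degradation
    expect_equal(unname(p["h"]), 4.0)
    expect_true(all(p[lin] == 0.01))
    expect_true(all(p[setdiff(names(p), c(lin, "h"))] == 1.0))
    expect_false("h" %in% searched_parameters(a))
  }
  # semi-dual Y transcription is constitutive: no searched affinity
  expect_false("K2" %in% searched_parameters("semi_dual"))
  expect_true("K2" %in% searched_parameters("dual"))
})

test_that("architectures have the stated dimensions and outputs", {
  expect_equal(clock_model("single")$n_equations, 3)
  for (a in c("semi_dual", "dual", "redundant"))
    expect_equal(clock_model(a)$n_equations, 6)
  expect_equal(clock_model("single")$output, "X_nuc")
  expect_equal(clock_model("dual")$output, "XY_nuc")
  expect_equal(clock_model("semi_dual")$output, "XY_nuc")
  expect_equal(clock_model("redundant")$output, c("X_nuc", "Y_nuc"))
})

test_that("derivatives at the zero state reduce to bare transcription", {
  m <- clock_model("single")
  d <- clock_derivatives(m, c(0, 0, 0))
  # repressor absent -> full transcription rate; nothing else moves
  expect_equal(unname(d), c(1.0, 0, 0))
  md <- clock_model("dual")
  dd <- clock_derivatives(md, rep(0, 6))
  expect_equal(unname(dd), c(1.0, 0, 1.0, 0, 0, 0))
})

test_that("semi-dual and dual differ only in the mRNA(Y) equation", {
  set.seed(4)
  p <- reference_parameters("dual")
  nm <- searched_parameters("dual")
  p[nm] <- p[nm] * 10^runif(length(nm), -1, 1)
  for (i in 1:5) {
    s <- runif(6, 0, 8)
    d_semi <- clock_derivatives(clock_model("semi_dual"), s, params = p)
    d_dual <- clock_derivatives(clock_model("dual"), s, params = p)
    expect_equal(d_semi[-3], d_dual[-3])
    # repressed Y transcription is at most the constitutive rate
    expect_lte(d_dual[[3]], d_semi[[3]])
  }
})

test_that("symmetric dual parameters give a structurally symmetric field", {
  p <- reference_parameters("dual")
  nm <- searched_parameters("dual")
  set.seed(5)
  p[nm] <- p[nm] * 10^runif(length(nm), -1, 1)
  pairs <- loop_pairs("dual")
  p[unname(pairs)] <- p[names(pairs)]   # rho = 0: Y loop copies X loop
  m <- clock_model("dual")
  s <- c(0.3, 1.7, 0.9, 0.2, 2.5, 4.1)
  swap <- s[c(3, 4, 1, 2, 5, 6)]        # exchange X- and Y-loop states
  d1 <- clock_derivatives(m, s, params = p)
  d2 <- clock_derivatives(m, swap, params = p)
  expect_equal(unname(d1[c(3, 4, 1, 2, 5, 6)]), unname(d2), tolerance = 1e-12)
})

test_that("compiled and R rate-law compositions agree", {
  set.seed(6)
  for (a in architectures()) {
    m <- clock_model(a)
    p <- m$params
    nm <- searched_parameters(a)
    p[nm] <- p[nm] * 10^runif(length(nm), -1, 1)
    for (light in c(0, 1)) {
      s <- runif(m$n_equations, 0, 10)
      delta <- 0.4
      dR <- clock_derivatives(m, s, params = p,
                              light_factor = 1 + delta * light)
      dC <- deSolve::DLLfunc(func = m$arch$derivfunc, dllname = "clockloops",
                             initfunc = m$arch$initfunc, times = 0,
                             y = c(setNames(s, m$species), light = light),
                             parms = c(p, delta = delta))$dy
      expect_equal(unname(dC[seq_len(m$n_equations)]), unname(dR),
                   tolerance = 1e-12)
      expect_equal(unname(dC[m$n_equations + 1]), 0)
    }
  }
})

test_that("missing or non-positive parameters are rejected by name", {
  p <- reference_parameters("single")
  expect_error(clock_model("single", p[-1]), "S1")
  expect_error(clock_model("single", c(p, bogus = 1)), "bogus")
  p["D2"] <- -1
  expect_error(clock_model("single", p), "positive")
})

test_that("y_loop_bounds reproduces the symmetry limits", {
  g <- c(0.1, 10)
  expect_equal(y_loop_bounds(2, 0, g), c(2, 2))
  expect_equal(y_loop_bounds(2, 99, g), c(0.1, 10))
  expect_equal(y_loop_bounds(2, 1, g), c(1, 4))   # band [x/(1+rho), x(1+rho)]
  expect_error(y_loop_bounds(20, 1, g), "outside")
  # interval width is non-decreasing in rho and always contains x
  set.seed(7)
  for (i in 1:20) {
    x <- 10^runif(1, -1, 1)
    rhos <- sort(runif(5, 0, 120))
    w <- vapply(rhos, function(r) diff(y_loop_bounds(x, r, g)), numeric(1))
    expect_true(all(diff(w) >= -1e-12))
    for (r in rhos) {
      b <- y_loop_bounds(x, r, g)
      expect_true(b[1] <= x && x <= b[2])
      expect_true(b[1] >= g[1] && b[2] <= g[2])
    }
  }
})

test_that("states stay non-negative from non-negative starts", {
  set.seed(8)
  for (a in architectures()) {
    m <- clock_model(a)
    p <- m$params
    nm <- searched_parameters(a)
    p[nm] <- p[nm] * 10^runif(length(nm), -1, 1)
    traj <- integrate_clock(m, p, horizon = 400, dt = 0.5, transient = 0)
    if (traj$ok) expect_gte(min(traj$states), -1e-6)
  }
})

test_that("a silenced Y loop reduces the redundant model to the single one", {
  p1 <- test_params("single")
  pr <- reference_parameters("redundant")
  # transplant the X loop; silence Y-gene transcription
  shared <- c("S1", "S2", "K1", "T1", "T2", "U1", "U2",
              "K2", "T3", "T4", "U3", "U4")
  pr[c("S1", "S2", "K1", "T1", "T2", "U1", "U2")] <-
    p1[c("S1", "S2", "K1", "T1", "T2", "U1", "U2")]
  pr[c("D1", "D2", "D3")] <- p1[c("D1", "D2", "D3")]
  pr[c("D7", "D8", "D9")] <- p1[c("D4", "D5", "D6")]
  pr[c("L1", "L2", "L3")] <- p1[c("L1", "L2", "L3")]
  pr["S3"] <- 1e-9
  ms <- clock_model("single")
  mr <- clock_model("redundant")
  t1 <- integrate_clock(ms, p1, horizon = 600, transient = 300)
  tr <- integrate_clock(mr, pr, horizon = 600, transient = 300,
                        init = c(0.1, 0.1, 0.1, 0, 0, 0))
  expect_true(t1$ok && tr$ok)
  expect_lt(max(abs(t1$states[, c("mRNA_X", "X", "X_nuc")] -
                    tr$states[, c("mRNA_X", "X", "X_nuc")])), 1e-5)
  # the output of the virtual single model is carried by the X loop alone
  expect_lt(max(abs(output_signal(ms, t1) - output_signal(mr, tr))), 1e-5)
})
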