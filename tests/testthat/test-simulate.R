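test_that("one logistic step substitutes directly into the map", {
  # x1' = 0.2*(3.6 - 0.72 - 0.05) with x1=0.2, x2=0.5, r1=3.6, C1=0.1
  p <- logistic_params(r1 = 3.6, r2 = 3.7, C1 = 0.1, C2 = 0, L = 2L,
                       transient = 0L)
  ts <- simulate_logistic_pair(p, x0 = c(0.2, 0.5))
  expect_equal(ts$values[1, ], c(x1 = 0.2, x2 = 0.5))
  expect_equal(unname(ts$values[2, "x1"]), 0.566)
  # uncoupled fixed point: r = 2, x = 0.5 stays put
  p2 <- logistic_params(r1 = 2, r2 = 3.7, C1 = 0, C2 = 0, L = 50L,
                        transient = 0L)
  ts2 <- simulate_logistic_pair(p2, x0 = c(0.5, 0.3))
  expect_true(all(ts2$values[, "x1"] == 0.5))
})

test_that("simulated logistic trajectories stay in [0,1] and reproduce", {
  p <- logistic_params(C1 = 0.05, C2 = 0.1, L = 500L, seed = 11L)
  a <- simulate_logistic_pair(p)
  b <- simulate_logistic_pair(p)
  expect_identical(a$values, b$values)
  expect_true(all(a$values >= 0 & a$values <= 1))
  expect_true(is.numeric(a$meta$resamples))
})

test_that("uncoupled map matches an independent recursion oracle", {
  p <- logistic_params(r1 = 3.6, C1 = 0, C2 = 0, L = 10000L, transient = 0L)
  x0 <- c(0.37, 0.61)
  ts <- simulate_logistic_pair(p, x0 = x0)
  oracle <- logistic_oracle(x0, 3.6, 3.7, 0, 0, 10000L)
  expect_equal(unname(ts$values[, "x1"]), oracle[, 1])
  expect_equal(mean(ts$values[, "x1"]), mean(oracle[, 1]), tolerance = 1e-3)
})

test_that("divergent parameters raise a simulation failure naming them", {
  # r = 4.2 escapes the unit interval from any interior start
  p <- logistic_params(r1 = 4.2, r2 = 3.7, L = 100L, seed = 1L)
  expect_error(simulate_logistic_pair(p), "r1=4.2")
})

test_that("network topologies match the chain/ring arrangement", {
  sp_chain <- network_spec("chain", n_nodes = 20L)
  A <- network_adjacency(sp_chain)
  expect_equal(sum(A), 19L)                 # n-1 directed edges
  expect_true(all(diag(A) == 0))
  expect_equal(which(A[1, ] == 1), 2L)
  sp_ring <- network_spec("ring", n_nodes = 20L)
  Ar <- network_adjacency(sp_ring)
  expect_equal(sum(Ar), 20L)                # n directed edges
  expect_true(all(colSums(Ar) == 1))        # every node has exactly one parent
})

test_that("zero coupling factorizes the network into independent maps", {
  sp <- network_spec("chain", n_nodes = 5L, coupling = 0)
  x0 <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  net <- simulate_logistic_network(sp, L = 200L, transient = 0L, x0 = x0)
  for (j in 1:5) {
    oracle <- logistic_oracle(c(x0[j], 0.5), sp$node_growth_rates[j], 3,
                              0, 0, 200L)[, 1]
    expect_equal(unname(net$values[, j]), oracle)
  }
})

test_that("a chain node is unaffected by its downstream nodes", {
  sp <- network_spec("chain", n_nodes = 4L, coupling = 0.1)
  x0a <- c(0.3, 0.4, 0.5, 0.6)
  x0b <- c(0.3, 0.7, 0.2, 0.9)              # same node-1 start, others differ
  a <- simulate_logistic_network(sp, L = 150L, transient = 0L, x0 = x0a)
  b <- simulate_logistic_network(sp, L = 150L, transient = 0L, x0 = x0b)
  expect_equal(a$values[, 1], b$values[, 1])   # node 1 has no parent
  expect_false(isTRUE(all.equal(a$values[, 2], b$values[, 2])))
})

test_that("Roessler-Lorenz vector field substitutes correctly", {
  # x1' = -a(x2 + x3) at x = (1,1,1), a = 6
  f <- statecausal:::rl_field_cpp(c(1, 1, 1, 0, 0, 0), 6, 0)
  expect_equal(f[1], -12)
  # y2' = 28*y1 - y2 - y1*y3 + C*x2^2 at y = (1,1,1), x2 = 2, C = 0.1
  f2 <- statecausal:::rl_field_cpp(c(0, 2, 0, 1, 1, 1), 6, 0.1)
  expect_equal(f2[5], 28 - 1 - 1 + 0.1 * 4)
})

test_that("Roessler-Roessler vector field substitutes correctly", {
  # y1' = -w2*y2 - y3 + C*(x1 - y1) at y = (1,1,1), x1 = 2, w2 = 1, C = 0.5
  f <- statecausal:::rr_field_cpp(c(2, 0, 0, 1, 1, 1), 1, 1,
                                  0.15, 0.15, 0.2, 0.2, 10, 0.5, 1L)
  expect_equal(f[4], -1 - 1 + 0.5 * (2 - 1))
  # x2' = w1*x1 + a1*x2
  expect_equal(f[2], 1 * 2 + 0.15 * 0)
})

test_that("the Lorenz response decouples exactly at C = 0", {
  s0 <- c(1, 1, 0.5, 2, 3, 20)
  full <- statecausal:::rk4_rossler_lorenz_cpp(s0, 6, 0, 0.005, 0L, 50L, 60L)
  # integrating from a different Roessler start must not move y at C = 0
  s0b <- c(-2, 0.5, 1.2, 2, 3, 20)
  alt <- statecausal:::rk4_rossler_lorenz_cpp(s0b, 6, 0, 0.005, 0L, 50L, 60L)
  expect_identical(full[, 4:6], alt[, 4:6])
  expect_false(isTRUE(all.equal(full[, 1:3], alt[, 1:3])))
})

test_that("identical uncoupled Roessler subsystems stay identical", {
  s0 <- c(1, -2, 0.5, 1, -2, 0.5)
  ts <- statecausal:::rk4_rossler_rossler_cpp(s0, 1, 1, 0.15, 0.15, 0.2, 0.2,
                                              10, 0, 0.005, 0L, 100L, 60L, 1L)
  expect_identical(ts[, 1:3], ts[, 4:6])
})

test_that("RK4 is step-size converged and agrees with an independent integrator", {
  s0 <- c(1, 1, 0.5, 2, 3, 20)
  a <- statecausal:::rk4_rossler_lorenz_cpp(s0, 6, 2, 0.005, 0L, 17L, 60L)
  b <- statecausal:::rk4_rossler_lorenz_cpp(s0, 6, 2, 0.0025, 0L, 17L, 120L)
  expect_lt(sqrt(mean((a - b)^2)), 1e-4)    # halving dt, ~5 time units
  rr1 <- statecausal:::rk4_rossler_rossler_cpp(s0, 1, 1, .15, .15, .2, .2,
                                               10, .1, 0.005, 0L, 66L, 60L, 1L)
  rr2 <- statecausal:::rk4_rossler_rossler_cpp(s0, 1, 1, .15, .15, .2, .2,
                                               10, .1, 0.0025, 0L, 66L, 120L, 1L)
  expect_lt(sqrt(mean((rr1 - rr2)^2)), 1e-4)  # ~20 time units
  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) {
    list(c(-6 * (y[2] + y[3]), 6 * (y[1] + 0.2 * y[2]),
           6 * (0.2 + y[3] * (y[1] - 5.7)),
           10 * (-y[4] + y[5]), 28 * y[4] - y[5] - y[4] * y[6] + 2 * y[2]^2,
           y[4] * y[5] - 8 / 3 * y[6]))
  }
  ref <- deSolve::rk4(s0, seq(0, 10, by = 0.005), f, NULL)
  idx <- seq(1, 2001, by = 60)
  a10 <- statecausal:::rk4_rossler_lorenz_cpp(s0, 6, 2, 0.005, 0L,
                                              length(idx), 60L)
  expect_lt(max(abs(ref[idx, -1] - a10)), 1e-8)
})

test_that("flow simulators are seed-reproducible with full provenance", {
  p <- rossler_lorenz_params(a = 6, C = 2, L = 100L, seed = 21L)
  a <- simulate_rossler_lorenz(p)
  b <- simulate_rossler_lorenz(p)
  expect_identical(a$values, b$values)
  expect_equal(a$meta$params$seed, 21L)
  q <- rossler_rossler_params(omega2 = 2, L = 100L, seed = 22L)
  expect_identical(simulate_rossler_rossler(q)$values,
                   simulate_rossler_rossler(q)$values)
  expect_equal(frequency_ratio(q), 0.5)
})

test_that("the driver's spectral peak tracks omega against a periodogram oracle", {
  for (om in c(1, 2)) {
    p <- rossler_rossler_params(omega1 = om, omega2 = om, C = 0, L = 4096L,
                                seed = 4L)
    x1 <- simulate_rossler_rossler(p)$values[, "x1"]
    sp <- stats::spec.pgram(stats::ts(x1, deltat = 0.3), taper = 0,
                            plot = FALSE, detrend = TRUE)
    fpk <- sp$freq[which.max(sp$spec)]
    # the Roessler main peak sits a few percent above omega/(2*pi)
    expect_lt(abs(fpk - om / (2 * pi)) / (om / (2 * pi)), 0.06)
  }
})
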