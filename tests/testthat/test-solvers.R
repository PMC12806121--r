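test_that("RK4 reproduces closed-form solutions", {
  # constant field
  tr <- solve_rk4(function(y) 0 * y, c(2, -3), t_end = 5, dt = 0.1)
  expect_true(all(tr$states[, 1] == 2) && all(tr$states[, 2] == -3))
  # linear decay to e^-1
  tr <- solve_rk4(function(y) -y, 1, t_end = 1, dt = 0.01)
  expect_equal(unname(tail(tr$states, 1)[1, 1]), exp(-1), tolerance = 1e-8)
  # an equilibrium is a fixed point of the discrete map
  E <- positive_equilibrium()$state
  tr <- solve_rk4(function(y) rhs_local(y, table1), E, t_end = 100, dt = 0.1)
  expect_lt(max(abs(sweep(tr$states, 2, E))), 1e-9)
})

test_that("RK4 order: halving dt shrinks the endpoint error ~16x", {
  err <- vapply(c(0.1, 0.05, 0.025), function(h) {
    tr <- solve_rk4(function(y) -y, 1, t_end = 1, dt = h)
    abs(tail(tr$states, 1) - exp(-1))
  }, numeric(1))
  expect_true(all(err[-1] < err[-3] / 10))
})

test_that("Caputo predictor-corrector matches the Mittag-Leffler oracle", {
  for (a in c(0.5, 0.8, 0.9)) {
    tr <- solve_caputo_pc(function(y) -y, 1, alpha = a, t_end = 1, dt = 1e-3)
    expect_equal(unname(tail(tr$states, 1)[1, 1]), mittag_leffler(a, -1),
                 tolerance = 1e-3)
  }
  # D^alpha y = 0 keeps the state constant for any order
  tr0 <- solve_caputo_pc(function(y) 0 * y, c(1, 4), alpha = 0.6,
                         t_end = 2, dt = 0.05)
  expect_true(all(tr0$states[, 1] == 1) && all(tr0$states[, 2] == 4))
})

test_that("Caputo endpoint error decreases monotonically with dt", {
  ref <- mittag_leffler(0.8, -1)
  err <- vapply(c(1e-1, 1e-2, 1e-3), function(h) {
    tr <- solve_caputo_pc(function(y) -y, 1, alpha = 0.8, t_end = 1, dt = h)
    abs(tail(tr$states, 1) - ref)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("alpha = 1 dispatches to RK4 exactly", {
  rhs <- function(y) rhs_local(y, table1)
  y0 <- c(0.75, 0.00285, 0.5, 0.00125, 0.1)
  t1 <- solve_caputo_pc(rhs, y0, alpha = 1, t_end = 50, dt = 0.01)
  t2 <- solve_rk4(rhs, y0, t_end = 50, dt = 0.01)
  expect_identical(t1$states, t2$states)
})

test_that("compiled Caputo driver agrees with the pure-R reference scheme", {
  rhs <- function(y) c(-y[1] + 0.1 * y[2], -0.5 * y[2])
  for (a in c(0.5, 0.9)) {
    trR <- solve_caputo_pc(rhs, c(1, 2), alpha = a, t_end = 2, dt = 0.01)
    trC <- fadnet:::cpp_generic_caputo(rhs, c(1, 2), a, 2, 0.01, 1L)
    expect_equal(trR$states, trC$states, tolerance = 1e-13,
                 ignore_attr = TRUE)
  }
})

test_that("compiled local integrator agrees with the generic R solvers", {
  y0 <- c(0.7, 0.01, 0.45, 0.01, 0.12)
  rhs6 <- function(y) c(rhs_local(y[1:5], table1),
                        rhs_damage(min(max(y[6], 0), 1), y[2], y[4], table1))
  trR <- solve_rk4(rhs6, c(y0, 0), t_end = 20, dt = 0.01)
  trC <- simulate_local(table1, y0, q0 = 0, alpha = 1, t_end = 20, dt = 0.01)
  expect_equal(trC$states, trR$states, tolerance = 1e-12, ignore_attr = TRUE)
  trRf <- solve_caputo_pc(rhs6, c(y0, 0), alpha = 0.8, t_end = 5, dt = 0.01)
  trCf <- simulate_local(table1, y0, q0 = 0, alpha = 0.8, t_end = 5, dt = 0.01)
  expect_equal(trCf$states, trRf$states, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("near-integer order approaches the memoryless trajectory", {
  y0 <- c(0.75, 0.00285, 0.5, 0.00125, 0.1)
  t99 <- simulate_local(table1, y0, alpha = 0.99, t_end = 50, dt = 0.01,
                        store_every = 5000)
  t100 <- simulate_local(table1, y0, alpha = 1, t_end = 50, dt = 0.01,
                         store_every = 5000)
  end99 <- tail(t99$states, 1)
  end100 <- tail(t100$states, 1)
  expect_lt(max(abs(end99 - end100)) / max(abs(end100)), 0.05)
})

test_that("Mittag-Leffler series satisfies its identities", {
  for (a in c(0.3, 0.5, 0.8, 1)) expect_equal(mittag_leffler(a, 0), 1)
  expect_equal(mittag_leffler(1, -1), exp(-1), tolerance = 1e-7)
  # E_{1/2}(-x) = exp(x^2) erfc(x) at x = 1; erfc via pnorm
  erfc1 <- 2 * stats::pnorm(1 * sqrt(2), lower.tail = FALSE)
  expect_equal(mittag_leffler(0.5, -1), exp(1) * erfc1, tolerance = 1e-10)
  expect_error(mittag_leffler(0.5, 50), "domain|series|10")
  expect_error(mittag_leffler(1.5, -1), "alpha")
})

test_that("blow-up is reported with the last finite time", {
  expect_error(solve_rk4(function(y) y^2, 2, t_end = 10, dt = 0.01),
               "blew up")
})
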