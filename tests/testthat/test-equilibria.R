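test_that("the branch cascade recovers the printed, trivial and disease-free equilibria", {
  eq <- find_equilibria(table1)
  states <- lapply(eq, `[[`, "state")
  has_point <- function(x, tol = 1e-6)
    any(vapply(states, function(s) max(abs(s - x)) < tol, logical(1)))
  # origin and the disease-free point (closed forms)
  expect_true(has_point(rep(0, 5)))
  expect_true(has_point(c(0.75, 0, 0.5, 0, 0.1)))
  # the printed positive equilibrium, to its printed precision
  expect_true(any(vapply(states, function(s)
    all(abs(s - c(0.596, 0.154, 0.33, 0.14, 0.1)) <
          c(1e-3, 1e-3, 5e-3, 5e-3, 1e-6)), logical(1))))
  # every returned point is a genuine equilibrium
  for (e in eq) {
    expect_lt(max(abs(rhs_local(e$state, table1))), 1e-10)
    expect_true(all(e$state >= 0))
  }
})

test_that("the seeded dynamics converge to the cascade's positive equilibrium (independent route)", {
  # long integration is an oracle for the root-finding: the attractor the
  # flow selects must be the interior cascade point
  E <- positive_equilibrium()$state
  tr <- simulate_local(table1, c(0.75, 0.00285, 0.5, 0.00125, 0.1),
                       alpha = 1, t_end = 400, dt = 0.01, store_every = 1000)
  expect_equal(unname(tail(tr$states, 1)[1, 1:5]), E, tolerance = 1e-5)
})

test_that("analytic Jacobian agrees with centered finite differences at random points", {
  set.seed(7)
  for (i in 1:100) {
    x <- runif(5, 0, 1.5)
    J <- ad_jacobian(x, table1)
    h <- 1e-6
    Jfd <- sapply(1:5, function(j) {
      e <- rep(0, 5); e[j] <- h
      (rhs_local(x + e, table1) - rhs_local(x - e, table1)) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd)), 1e-6)
    # structural zeros of the amyloid row
    expect_identical(unname(J[1, 3:5]), c(0, 0, 0))
  }
})

test_that("closed-form Jacobian entries at notable points", {
  E <- positive_equilibrium()$state
  expect_equal(ad_jacobian(E, table1)[5, 5], -1)         # c0 - 2 w*/c1
  Jdf <- ad_jacobian(c(0.75, 0, 0.5, 0, 0.1), table1)
  expect_equal(Jdf[2, 2], 0.197)                          # unstable direction
})

test_that("stability verdicts: positive equilibrium stable, disease-free unstable", {
  E <- positive_equilibrium()
  v1 <- classify_stability(E, table1, alpha = 1)
  expect_true(v1$stable)
  expect_identical(v1$criterion, "real-part")
  expect_true(all(Re(v1$eigenvalues) < 0))
  for (a in c(0.9, 0.8)) {
    va <- classify_stability(E, table1, alpha = a)
    expect_true(va$stable)
    expect_identical(va$criterion, "argument")
    expect_true(all(abs(Arg(va$eigenvalues)) > a * pi / 2))
  }
  vdf <- classify_stability(c(0.75, 0, 0.5, 0, 0.1), table1, alpha = 1)
  expect_false(vdf$stable)
})

test_that("fractional stability is monotone in alpha and matches real-part at alpha = 1", {
  E <- positive_equilibrium()
  alphas <- seq(0.99, 0.05, by = -0.02)
  margins <- vapply(alphas, function(a)
    classify_stability(E, table1, alpha = a)$margin, numeric(1))
  # argument margin grows as alpha shrinks: stable once, stable for all smaller
  expect_true(all(diff(margins) > 0))
  expect_true(all(margins > 0))
  # the two criteria agree at the integer-order limit on random model points
  set.seed(11)
  for (i in 1:100) {
    x <- runif(5, 0, 1.2)
    ev <- eigen(ad_jacobian(x, table1), only.values = TRUE)$values
    if (any(abs(Re(ev)) < 1e-6)) next  # skip near-marginal spectra
    expect_identical(all(Re(ev) < 0), all(abs(Arg(ev)) > pi / 2))
  }
})

test_that("tauopathy classification follows the invasion condition", {
  expect_identical(classify_tauopathy(table1), "secondary")
  expect_identical(classify_tauopathy(ad_params(b2 = 1.6)), "primary")
  # non-strict boundary: b2 * b0/b1 == b1_tilde stays secondary
  p <- ad_params(b2 = table1$b1_tilde * table1$b1 / table1$b0)
  expect_identical(classify_tauopathy(p), "secondary")
  expect_error(classify_tauopathy(ad_params(b1 = 0)), "b1")
})

test_that("equilibria export to JSON with [re, im] eigenvalue pairs", {
  eq <- find_equilibria(table1)
  js <- jsonlite::fromJSON(equilibria_to_json(eq, table1, alpha = 0.8),
                           simplifyVector = FALSE)
  expect_length(js, length(eq))
  expect_length(js[[1]]$eigenvalues, 5L)
  expect_length(js[[1]]$eigenvalues[[1]], 2L)
  expect_identical(js[[1]]$criterion, "argument")
})
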