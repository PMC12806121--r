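test_that("a single isolated node reduces to the local model with damage", {
  cat_map <- brain_id_catalogue()
  nodes <- data.frame(id = "solo", x = 0, y = 0, z = 0,
                      brain_id = "entorhinal", region = "limbic")
  con <- connectome(nodes, data.frame(source = character(0),
                                      target = character(0),
                                      n_fibers = numeric(0),
                                      length_mm = numeric(0)))
  lap <- build_laplacians(build_adjacency(con), table1)
  rhs <- assemble_network_rhs(con, lap, network_params(table1))
  y <- c(0.7, 0.05, 0.4, 0.02, 0.09, 0.1)
  expect_equal(rhs(y), c(rhs_local(y[1:5], table1),
                         rhs_damage(y[6], y[2], y[4], table1)),
               tolerance = 1e-14)
})

test_that("the homogeneous positive equilibrium is a network fixed point", {
  con <- fixture_graphs()$toy12
  E <- positive_equilibrium()$state
  lap <- build_laplacians(build_adjacency(con), table1)
  rhs <- assemble_network_rhs(con, lap, network_params(table1))
  y <- unlist(lapply(c(E, 0), rep, nrow(con$nodes)))
  expect_lt(max(abs(rhs(y)[1:(5 * 12)])), 1e-12)
  # and the compiled integrator does not drift off it
  tr <- simulate_network(con, table1, alpha = 1, t_end = 100, dt = 0.01,
                         init = homogeneous_state(con, E), store_every = 1000)
  drift <- max(abs(sweep(tr$states[, 1:(5 * 12)], 2,
                         rep(E, each = 12))))
  expect_lt(drift, 1e-9)
})

test_that("compiled network field matches the R closure on a heterogeneous run", {
  con <- fixture_graphs()$toy12
  np <- mixed_tauopathy_overrides(con, list(entorhinal = c(b2 = 1.6, b3 = 3)))
  lap <- build_laplacians(build_adjacency(con), np$base)
  rhs <- assemble_network_rhs(con, lap, np)
  init <- make_initial_condition(con)
  y0 <- unlist(init, use.names = FALSE)
  trR <- solve_rk4(rhs, y0, t_end = 5, dt = 0.01)
  trC <- simulate_network(con, np, alpha = 1, t_end = 5, dt = 0.01,
                          init = init, store_every = 1L)
  expect_equal(trC$states, trR$states, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("seeded initial conditions follow the relative-percentage convention", {
  con <- fixture_graphs()$toy12
  st <- make_initial_condition(con)
  ia <- match(con$seeds$abeta, con$nodes$id)
  it <- match(con$seeds$tau, con$nodes$id)
  expect_equal(unique(st$u_tilde[ia]), 0.0038 * 0.75)   # = 0.00285
  expect_equal(unique(st$v_tilde[it]), 0.0025 * 0.5)
  # nodes outside both seed sets are clean
  out <- setdiff(seq_len(12), c(ia, it))
  expect_true(all(st$u_tilde[out] == 0) && all(st$v_tilde[out] == 0))
  expect_true(all(st$u == 0.75) && all(st$v == 0.5) && all(st$w == 0.1) &&
                all(st$q == 0))
  # absolute mode
  sta <- make_initial_condition(con, mode = "absolute")
  expect_equal(unique(sta$u_tilde[ia]), 0.0038)
  # unseeded state stays toxic-free under simulation (invariant subspace)
  st0 <- make_initial_condition(con, seed_fraction_abeta = 0,
                                seed_fraction_tau = 0)
  tr <- simulate_network(con, table1, alpha = 1, t_end = 20, dt = 0.01,
                         init = st0, store_every = 200)
  expect_true(all(species_block(tr, con, "u_tilde") == 0))
  expect_true(all(species_block(tr, con, "v_tilde") == 0))
  expect_true(all(species_block(tr, con, "q") == 0))
})

test_that("zero diffusivity decouples every node to its isolated trajectory", {
  con <- fixture_graphs()$path3
  p <- ad_params(rho_u = 0, rho_u_tilde = 0, rho_v = 0, rho_v_tilde = 0)
  init <- make_initial_condition(con)
  tr <- simulate_network(con, p, alpha = 1, t_end = 30, dt = 0.01,
                         init = init, store_every = 300)
  for (j in 1:3) {
    y0j <- c(init$u[j], init$u_tilde[j], init$v[j], init$v_tilde[j],
             init$w[j])
    trj <- simulate_local(p, y0j, q0 = 0, alpha = 1, t_end = 30, dt = 0.01,
                          store_every = 300)
    netj <- tr$states[, j + 3 * (0:5)]
    expect_equal(netj, unname(trj$states), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("seeded uniform run converges to the homogeneous attractor with saturating damage", {
  con <- fixture_graphs()$toy12
  E <- positive_equilibrium()$state
  tr <- simulate_network(con, table1, alpha = 1, t_end = 1500, dt = 0.01,
                         store_every = 2000)
  terminal <- tail(tr$states, 1)[1, ]
  expect_lt(max(abs(terminal[1:(5 * 12)] - rep(E, each = 12))), 1e-2)
  q_end <- terminal[(5 * 12 + 1):(6 * 12)]
  expect_true(all(q_end > 0.95))
  # damage is node-wise nondecreasing in time
  q_block <- species_block(tr, con, "q")
  expect_true(all(apply(q_block, 2, function(col) all(diff(col) >= -1e-12))))
})

test_that("mixed-tauopathy override expansion and errors", {
  con <- fixture_graphs()$toy12
  expect_error(mixed_tauopathy_overrides(con, list(precuneus = c(b2 = 2))),
               "precuneus")
  np0 <- mixed_tauopathy_overrides(con, list())
  expect_length(np0$overrides, 0)
  # overriding every node with the base values is a no-op
  ids <- unique(con$nodes$brain_id)
  spec <- setNames(rep(list(c(b2 = table1$b2, b3 = table1$b3)), length(ids)),
                   ids)
  np <- mixed_tauopathy_overrides(con, spec)
  expect_equal(fadnet:::params_matrix(np, con),
               fadnet:::params_matrix(network_params(table1), con))
  expect_error(network_params(table1, list(t01 = c(b2 = -5))), "invalid")
  expect_error(
    simulate_network(con, network_params(table1, list(ghost = c(b2 = 1))),
                     t_end = 1, dt = 0.1),
    "unknown node")
})

test_that("group summaries average correctly and rank by terminal toxic tau", {
  con <- fixture_graphs()$toy12
  E <- positive_equilibrium()$state
  tr <- simulate_network(con, table1, alpha = 1, t_end = 1, dt = 0.1,
                         init = homogeneous_state(con, E), store_every = 1L)
  s <- summarize_trajectory(tr, con, grouping = "region")
  # uniform state: every group equals the node value
  for (v in c("u_tilde", "v_tilde")) {
    vals <- s$value[s$variable == v]
    expect_equal(vals, rep(E[match(v, c("u", "u_tilde", "v", "v_tilde"))],
                           length(vals)), tolerance = 1e-9)
  }
  # synthetic two-group ranking
  st <- homogeneous_state(con, E)
  st$v_tilde[con$nodes$region == "limbic"] <- 0.2
  st$v_tilde[con$nodes$region == "frontal"] <- 0.1
  tr2 <- simulate_network(con, diffusion_only_params(), alpha = 1,
                          t_end = 0.1, dt = 0.1, init = st, store_every = 1L)
  s2 <- summarize_trajectory(tr2, con, grouping = "region")
  expect_identical(attr(s2, "ranking"), c("limbic", "frontal"))
})
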