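test_that("adjacency weights are fiber count over squared length", {
  fx <- fixture_graphs()
  A <- build_adjacency(fx$two_node)
  expect_equal(A[1, 2], 1)           # 4 / 2^2
  expect_equal(A, t(A))
  expect_true(all(diag(A) == 0))
  # triangle: weighted degree of the shared node is the sum of its weights
  cat_map <- c("entorhinal", "precuneus", "superiorfrontal")
  nodes <- data.frame(id = c("a", "b", "c"), x = 0, y = 0, z = 0,
                      brain_id = cat_map,
                      region = c("limbic", "parietal", "frontal"))
  edges <- data.frame(source = c("a", "a", "b"), target = c("b", "c", "c"),
                      n_fibers = c(1, 2, 3), length_mm = 1)
  A3 <- build_adjacency(connectome(nodes, edges))
  expect_equal(sum(A3["a", ]), 3)
  # empty edge set gives the zero matrix
  A0 <- build_adjacency(connectome(nodes, edges[0, ]))
  expect_true(all(A0 == 0))
})

test_that("Laplacians are scaled graph Laplacians: zero row sums, PSD, correct 2-node form", {
  p <- table1
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  L <- build_laplacians(A, ad_params(rho_u = 1))
  expect_equal(L$u, matrix(c(1, -1, -1, 1), 2, 2))
  con <- generate_connectome(generator_spec(n_nodes = 40, seed = 3))
  lap <- build_laplacians(build_adjacency(con), p)
  for (s in names(lap)) {
    L <- lap[[s]]
    expect_lt(max(abs(rowSums(L))), 1e-12)
    expect_equal(L, t(L))
    expect_true(all(L[row(L) != col(L)] <= 0))
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_lt(min(abs(ev)), 1e-10)   # constant vector in the kernel
  }
  # rho = 0 decouples the network
  L0 <- build_laplacians(A, ad_params(rho_u = 0))
  expect_true(all(L0$u == 0))
  expect_error(build_laplacians(A, ad_params(rho_u = -1)), "invalid|negative")
})

test_that("region averaging is the grouped mean and a convex combination", {
  expect_equal(unname(region_average(c(5, 5, 5), c("a", "b", "a"))), c(5, 5))
  expect_equal(region_average(c(0.1, 0.3), c("g", "g"))[["g"]], 0.2)
  avg <- region_average(c(1, 0, 1), c("a", "b", "b"))
  expect_equal(unname(avg[c("a", "b")]), c(1.0, 0.5))
  set.seed(5)
  x <- runif(50); g <- sample(letters[1:4], 50, replace = TRUE)
  m <- region_average(x, g)
  for (gr in names(m)) {
    expect_gte(m[[gr]], min(x[g == gr]))
    expect_lte(m[[gr]], max(x[g == gr]))
  }
  expect_error(region_average(1:3, c("a", "b")), "equal length")
})

test_that("connectome CSV round trip is exact and validation reports offending rows", {
  con <- generate_connectome(generator_spec(n_nodes = 30, seed = 9,
                                            edges_per_node = 6))
  nf <- tempfile(fileext = ".csv"); ef <- tempfile(fileext = ".csv")
  write_connectome(con, nf, ef)
  con2 <- read_connectome(nf, ef, quiet = TRUE)
  expect_identical(con$nodes, con2$nodes)
  expect_identical(con$edges, con2$edges)
  expect_identical(con$seeds, con2$seeds)
  # a second round trip is byte-identical
  nf2 <- tempfile(fileext = ".csv"); ef2 <- tempfile(fileext = ".csv")
  write_connectome(con2, nf2, ef2)
  expect_identical(readLines(nf), readLines(nf2))
  expect_identical(readLines(ef), readLines(ef2))

  nodes <- con$nodes; edges <- con$edges
  # self-loop names the row
  bad <- edges; bad$target[3] <- bad$source[3]
  expect_error(connectome(nodes, bad), "self-loop.*3")
  # duplicate edge names the row
  bad <- rbind(edges, edges[1, ])
  expect_error(connectome(nodes, bad), paste0("duplicate.*", nrow(bad)))
  # unknown region label
  badn <- nodes; badn$region[2] <- "cerebellum"
  expect_error(connectome(badn, edges), "region")
  # missing column
  expect_error(connectome(nodes[, -4], edges), "missing column")
  expect_error(connectome(nodes, transform(edges, length_mm = 0)), "positive")
})

test_that("pure diffusion conserves per-species totals on the network", {
  con <- fixture_graphs()$path3
  p <- diffusion_only_params()
  lap <- build_laplacians(build_adjacency(con), p)
  rhs <- assemble_network_rhs(con, lap, network_params(p))
  y0 <- c(c(1, 2, 3), c(0.5, 0, 0), c(0, 1, 0), c(0.2, 0.1, 0),
          c(0, 0, 0), c(0, 0, 0))
  # field sums to zero per diffusing species
  f <- rhs(y0)
  for (k in 1:4) expect_lt(abs(sum(f[(3 * k - 2):(3 * k)])), 1e-12)
  tr <- solve_rk4(rhs, y0, t_end = 10, dt = 0.01)
  totals <- sapply(1:4, function(k)
    rowSums(tr$states[, (3 * k - 2):(3 * k), drop = FALSE]))
  expect_lt(max(abs(sweep(totals, 2, totals[1, ]))), 1e-10)
})
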