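# shared fixtures for the test suite

table1 <- ad_params()

# the positive (all components > 0) equilibrium from the cascade
positive_equilibrium <- function(params = table1) {
  eq <- find_equilibria(params)
  pos <- Filter(function(e) all(e$state > 1e-9), eq)
  expect_length(pos, 1L)
  pos[[1L]]
}

# closed-form toxic-amyloid level of the interior equilibrium as a function
# of the astrocyte parameters (independent oracle for the dual-role study)
ut_star_oracle <- function(p) {
  (p$a2 * p$a0 / p$a1 - p$a1_tilde - p$mu * p$c0 * p$c1) /
    (p$a2^2 / p$a1 - p$mu)
}

# reaction-free parameter set (pure diffusion); c1 kept positive
diffusion_only_params <- function(base = table1) {
  ad_params(a0 = 0, a1 = 0, a2 = 0, a1_tilde = 0,
            b0 = 0, b1 = 0, b2 = 0, b1_tilde = 0, b3 = 0,
            c0 = 0, c1 = base$c1, mu = 0,
            k1 = 0, k2 = 0, k3 = 0, k4 = 0,
            rho_u = base$rho_u, rho_u_tilde = base$rho_u_tilde,
            rho_v = base$rho_v, rho_v_tilde = base$rho_v_tilde)
}

# homogeneous network state with every node at `state5` and damage q0
homogeneous_state <- function(con, state5, q0 = 0) {
  st <- make_initial_condition(con, seed_fraction_abeta = 0,
                               seed_fraction_tau = 0,
                               baseline = c(u = 1, v = 1, w = 1))
  st$u[] <- state5[1]; st$u_tilde[] <- state5[2]
  st$v[] <- state5[3]; st$v_tilde[] <- state5[4]
  st$w[] <- state5[5]; st$q[] <- q0
  st
}

species_block <- function(traj, con, species) {
  N <- nrow(con$nodes)
  k <- match(species, c("u", "u_tilde", "v", "v_tilde", "w", "q"))
  traj$states[, ((k - 1L) * N + 1L):(k * N), drop = FALSE]
}

first_crossing <- function(times, values, level) {
  i <- which(values >= level)[1L]
  expect_false(is.na(i))
  if (i == 1L) return(times[1L])
  # linear interpolation within the bracketing interval
  t0 <- times[i - 1L]; t1 <- times[i]
  v0 <- values[i - 1L]; v1 <- values[i]
  t0 + (level - v0) / (v1 - v0) * (t1 - t0)
}
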