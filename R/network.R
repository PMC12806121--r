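# column order of the per-node parameter matrix handed to the C++ drivers;
# must match the Par enum in src/solvers.cpp
local_param_names <- c("a0", "a1", "a2", "a1_tilde", "b0", "b1", "b2",
                       "b1_tilde", "b3", "c0", "c1", "mu",
                       "k1", "k2", "k3", "k4")

#' Per-node parameter set for heterogeneous (mixed-tauopathy) networks
#'
#' Couples a base [ad_params()] set with partial per-node overrides.  Nodes
#' without an override use the base values; overridden nodes replace any
#' subset of the local reaction/damage parameters (typically \code{b2} and
#' \code{b3}, which set the tauopathy class of the node).
#'
#' @param base an [ad_params()] object.
#' @param overrides named list: node id -> named numeric vector/list of
#'   parameter overrides.
#' @return An object of class \code{network_params}.
#' @export
network_params <- function(base, overrides = list()) {
  base <- stop_if_invalid(as_ad_params(base))
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("`overrides` must be named by node id")
    for (id in names(overrides)) {
      ov <- overrides[[id]]
      unknown <- setdiff(names(ov), local_param_names)
      if (length(unknown))
        stop("override for node '", id, "' names unknown parameter(s): ",
             paste(unknown, collapse = ", "))
      merged <- base
      merged[names(ov)] <- as.list(as.numeric(unlist(ov)))
      stop_if_invalid(merged)
      overrides[[id]] <- as.list(as.numeric(unlist(ov)))
      names(overrides[[id]]) <- names(ov)
    }
  }
  structure(list(base = base, overrides = overrides),
            class = "network_params")
}

as_network_params <- function(x) {
  if (inherits(x, "network_params")) return(x)
  network_params(as_ad_params(x))
}

# N x 16 per-node parameter matrix in C++ column order
params_matrix <- function(net_params, con) {
  net_params <- as_network_params(net_params)
  ids <- con$nodes$id
  unknown <- setdiff(names(net_params$overrides), ids)
  if (length(unknown))
    stop("override references unknown node id(s): ",
         paste(unknown, collapse = ", "))
  base_row <- unlist(net_params$base[local_param_names])
  P <- matrix(base_row, nrow = length(ids), ncol = length(base_row),
              byrow = TRUE, dimnames = list(ids, local_param_names))
  for (id in names(net_params$overrides)) {
    ov <- net_params$overrides[[id]]
    P[id, names(ov)] <- unlist(ov)
  }
  P
}

#' Network right-hand side as an R closure
#'
#' Builds the full 6N-dimensional vector field of the connectome model: each
#' node evolves under the local reaction terms (with its own parameters) plus
#' graph-Laplacian diffusion \code{-(L_s y_s)_j} for the four mobile species;
#' the astrocyte field w and the damage field q are strictly local.  This is
#' the transparent reference implementation used in tests; [simulate_network()]
#' runs the equivalent compiled version.
#'
#' The state layout is six stacked blocks of length N:
#' \code{(u, u_tilde, v, v_tilde, w, q)}.
#'
#' @param con a [connectome()].
#' @param laplacians a \code{laplacian_set} from [build_laplacians()].
#' @param net_params a [network_params()] object (or an [ad_params()]).
#' @return A function mapping a 6N state vector to its derivative.
#' @export
assemble_network_rhs <- function(con, laplacians, net_params) {
  stopifnot(inherits(con, "connectome"), inherits(laplacians, "laplacian_set"))
  P <- params_matrix(net_params, con)
  N <- nrow(con$nodes)
  Lu <- laplacians$u; Lut <- laplacians$u_tilde
  Lv <- laplacians$v; Lvt <- laplacians$v_tilde
  if (!all(vapply(list(Lu, Lut, Lv, Lvt), nrow, 1L) == N))
    stop("Laplacian dimension does not match the connectome")
  idx <- function(k) ((k - 1L) * N + 1L):(k * N)
  function(y) {
    u <- y[idx(1)]; ut <- y[idx(2)]; v <- y[idx(3)]
    vt <- y[idx(4)]; w <- y[idx(5)]; q <- y[idx(6)]
    unname(c(
      u * (P[, "a0"] - P[, "a1"] * u) - P[, "a2"] * u * ut - drop(Lu %*% u),
      -P[, "a1_tilde"] * ut + P[, "a2"] * u * ut -
        P[, "mu"] * ut * (w - ut) - drop(Lut %*% ut),
      v * (P[, "b0"] - P[, "b1"] * v) - P[, "b2"] * v * vt -
        P[, "b3"] * ut * v * vt - drop(Lv %*% v),
      -P[, "b1_tilde"] * vt + P[, "b2"] * v * vt +
        P[, "b3"] * ut * v * vt - drop(Lvt %*% vt),
      w * (P[, "c0"] - w / P[, "c1"]),
      (1 - q) * (P[, "k1"] * ut + P[, "k2"] * vt +
                   P[, "k3"] * ut * vt + P[, "k4"] * q)))
  }
}

#' Seeded initial condition for a network run
#'
#' Every node starts at the healthy baseline (healthy amyloid u, healthy tau
#' v, astrocytes w, zero toxic load, zero damage).  Nodes in the
#' amyloid-beta seed set receive a toxic amyloid seed and nodes in the tau
#' seed set a toxic tau seed.  In \code{"relative"} mode (default) the seed
#' magnitudes are fractions of the node's healthy baseline (0.38% of u for
#' toxic amyloid, 0.25% of v for toxic tau); in \code{"absolute"} mode the
#' fractions are used as raw concentrations.
#'
#' @param con a [connectome()] with non-empty seed sets.
#' @param baseline named vector with healthy baselines \code{u}, \code{v},
#'   \code{w}; defaults to the disease-free state
#'   (a0/a1, b0/b1, c0*c1) of the default parameters.
#' @param seed_fraction_abeta,seed_fraction_tau seed magnitudes.
#' @param mode \code{"relative"} or \code{"absolute"}.
#' @return A \code{network_state}: list of per-node vectors
#'   \code{u, u_tilde, v, v_tilde, w, q}.
#' @export
make_initial_condition <- function(con,
                                   baseline = c(u = 0.75, v = 0.5, w = 0.1),
                                   seed_fraction_abeta = 0.0038,
                                   seed_fraction_tau = 0.0025,
                                   mode = c("relative", "absolute")) {
  stopifnot(inherits(con, "connectome"))
  mode <- match.arg(mode)
  if (!all(c("u", "v", "w") %in% names(baseline)))
    stop("`baseline` must name u, v and w")
  if (seed_fraction_abeta < 0 || seed_fraction_tau < 0)
    stop("seed fractions must be nonnegative")
  if ((seed_fraction_abeta > 0 && length(con$seeds$abeta) == 0) ||
      (seed_fraction_tau > 0 && length(con$seeds$tau) == 0))
    stop("empty seed set: no toxic propagation can start")
  N <- nrow(con$nodes)
  st <- list(u = rep(unname(baseline["u"]), N),
             u_tilde = rep(0, N),
             v = rep(unname(baseline["v"]), N),
             v_tilde = rep(0, N),
             w = rep(unname(baseline["w"]), N),
             q = rep(0, N))
  ia <- node_index(con, con$seeds$abeta)
  it <- node_index(con, con$seeds$tau)
  if (mode == "relative") {
    st$u_tilde[ia] <- seed_fraction_abeta * st$u[ia]
    st$v_tilde[it] <- seed_fraction_tau * st$v[it]
  } else {
    st$u_tilde[ia] <- seed_fraction_abeta
    st$v_tilde[it] <- seed_fraction_tau
  }
  structure(st, class = "network_state", node_ids = con$nodes$id)
}

flatten_state <- function(st) unlist(st, use.names = FALSE)

#' Simulate the full connectome model
#'
#' Integrates the 6N-dimensional network system (four diffusing protein
#' species, local astrocytes, local damage) with RK4 for \code{alpha = 1}
#' and the Caputo Adams-Bashforth-Moulton predictor-corrector for
#' \code{0 < alpha < 1}.  Both paths run compiled code; the fractional path
#' retains the full memory kernel, so its cost grows quadratically with the
#' number of steps.
#'
#' @param con a [connectome()].
#' @param net_params a [network_params()] or [ad_params()] object.
#' @param alpha fractional order in (0, 1].
#' @param t_end,dt time horizon and step.
#' @param init a \code{network_state} from [make_initial_condition()];
#'   default builds one with the standard baselines and seed fractions.
#' @param store_every store every k-th step (thinning; the integration step
#'   is unaffected).
#' @return An \code{ad_trajectory} whose \code{states} matrix has 6N columns
#'   (blocks u, u_tilde, v, v_tilde, w, q of length N); meta carries the node
#'   ids, the layout, and a convergence flag (sup-norm change over the final
#'   5\% of the horizon below 1e-6).
#' @export
simulate_network <- function(con, net_params, alpha = 1, t_end = 400,
                             dt = 0.01, init = NULL, store_every = 10L) {
  stopifnot(inherits(con, "connectome"))
  net_params <- as_network_params(net_params)
  check_grid(t_end, dt)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (is.null(init)) init <- make_initial_condition(con)
  stopifnot(inherits(init, "network_state"))
  P <- params_matrix(net_params, con)
  lap <- build_laplacians(build_adjacency(con), net_params$base)
  y0 <- flatten_state(init)
  thin <- as.integer(store_every)
  res <- if (alpha == 1) {
    cpp_network_rk4(y0, P, lap$u, lap$u_tilde, lap$v, lap$v_tilde,
                    t_end, dt, thin)
  } else {
    cpp_network_caputo(y0, P, lap$u, lap$u_tilde, lap$v, lap$v_tilde,
                       alpha, t_end, dt, thin)
  }
  states <- res$states
  times <- drop(res$times)
  tail_idx <- which(times >= 0.95 * max(times))
  conv <- length(tail_idx) >= 2 &&
    max(abs(states[max(tail_idx), ] - states[min(tail_idx), ])) < 1e-6
  new_trajectory(times, states,
                 alpha = alpha, dt = dt,
                 solver = if (alpha == 1) "rk4" else "caputo-abm-pece",
                 extra = list(node_ids = con$nodes$id,
                              species = c("u", "u_tilde", "v", "v_tilde",
                                          "w", "q"),
                              converged = conv))
}

#' Simulate the single-compartment (temporal) model with damage
#'
#' Compiled integration of the five concentration equations plus the damage
#' equation at one node (no diffusion), by RK4 (\code{alpha = 1}) or the
#' Caputo predictor-corrector (\code{alpha < 1}).
#'
#' @param params an [ad_params()] object.
#' @param y0 initial \code{(u, u_tilde, v, v_tilde, w)}.
#' @param q0 initial damage in [0, 1].
#' @param alpha fractional order in (0, 1]; defaults to \code{params$alpha}.
#' @param t_end,dt horizon and step.
#' @param store_every thinning factor for the stored trajectory.
#' @return An \code{ad_trajectory} with 6 columns
#'   \code{(u, u_tilde, v, v_tilde, w, q)}.
#' @export
simulate_local <- function(params, y0, q0 = 0, alpha = NULL, t_end = 400,
                           dt = 0.01, store_every = 1L) {
  params <- stop_if_invalid(as_ad_params(params))
  if (is.null(alpha)) alpha <- params$alpha
  if (!is.numeric(y0) || length(y0) != 5L || any(!is.finite(y0)))
    stop("`y0` must be a finite numeric 5-vector")
  if (q0 < 0 || q0 > 1) stop("`q0` must lie in [0, 1]")
  check_grid(t_end, dt)
  pv <- unlist(params[local_param_names])
  full0 <- c(y0, q0)
  res <- if (alpha == 1) {
    cpp_local_rk4(full0, pv, t_end, dt, as.integer(store_every))
  } else {
    cpp_local_caputo(full0, pv, alpha, t_end, dt, as.integer(store_every))
  }
  st <- res$states
  colnames(st) <- c("u", "u_tilde", "v", "v_tilde", "w", "q")
  new_trajectory(drop(res$times), st, alpha = alpha, dt = dt,
                 solver = if (alpha == 1) "rk4" else "caputo-abm-pece")
}

#' Integrate the damage equation under fixed toxic loads
#'
#' Drives \code{D^alpha q = (1-q)(k1*ut + k2*vt + k3*ut*vt + k4*q)} with the
#' toxic concentrations held constant, as when the protein system has settled
#' at its equilibrium.  Useful for studying the approach of q to its
#' absorbing state q = 1 and how the fractional order delays it.
#'
#' @param params an [ad_params()] object (damage weights k1..k4).
#' @param u_tilde,v_tilde fixed toxic loads (>= 0).
#' @param q0 initial damage.
#' @param alpha fractional order in (0, 1].
#' @param t_end,dt horizon and step.
#' @param store_every thinning factor.
#' @return An \code{ad_trajectory} with a single column q.
#' @export
simulate_damage <- function(params, u_tilde, v_tilde, q0 = 0, alpha = 1,
                            t_end = 2000, dt = 0.01, store_every = 10L) {
  params <- stop_if_invalid(as_ad_params(params))
  if (u_tilde < 0 || v_tilde < 0) stop("toxic loads must be nonnegative")
  if (q0 < 0 || q0 > 1) stop("`q0` must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("`alpha` must lie in (0, 1]")
  check_grid(t_end, dt)
  pv <- unlist(params[local_param_names])
  res <- cpp_damage_driven(q0, u_tilde, v_tilde, pv, alpha, t_end, dt,
                           as.integer(store_every))
  st <- res$states
  colnames(st) <- "q"
  new_trajectory(drop(res$times), st, alpha = alpha, dt = dt,
                 solver = if (alpha == 1) "rk4" else "caputo-abm-pece")
}

#' Expand brain-ID level (b2, b3) heterogeneity into node overrides
#'
#' Mixed tauopathy assigns different tau conversion/coupling parameters to
#' different brain IDs.  This helper expands a brain-ID level specification
#' into the node-level overrides consumed by [network_params()].
#'
#' @param con a [connectome()].
#' @param region_spec named list: brain ID -> named vector with entries
#'   \code{b2} and/or \code{b3} (other local parameters are allowed too).
#' @param base an [ad_params()] object for the non-overridden nodes.
#' @return A [network_params()] object.
#' @examples
#' con <- fixture_graphs()$toy12
#' np <- mixed_tauopathy_overrides(con, list(entorhinal = c(b2 = 1.6)))
#' @export
mixed_tauopathy_overrides <- function(con, region_spec, base = ad_params()) {
  stopifnot(inherits(con, "connectome"))
  if (length(region_spec) == 0)
    return(network_params(base))
  if (is.null(names(region_spec)) || any(names(region_spec) == ""))
    stop("`region_spec` must be named by brain ID")
  unknown <- setdiff(names(region_spec), unique(con$nodes$brain_id))
  if (length(unknown))
    stop("brain ID(s) not present in connectome: ",
         paste(unknown, collapse = ", "))
  overrides <- list()
  for (bid in names(region_spec)) {
    spec <- region_spec[[bid]]
    ids <- con$nodes$id[con$nodes$brain_id == bid]
    for (id in ids) overrides[[id]] <- as.list(spec)
  }
  network_params(base, overrides)
}

#' Group-averaged time series from a network trajectory
#'
#' Applies the region-averaging statistic at every stored time point to the
#' toxic amyloid, toxic tau and damage fields, returning a long data frame.
#' Groups are ranked by their terminal average toxic tau load (descending),
#' mirroring the region-ordering analysis of heterogeneous runs.
#'
#' @param traj an \code{ad_trajectory} from [simulate_network()].
#' @param con the [connectome()] that produced it.
#' @param grouping \code{"region"}, \code{"brain_id"}, or a custom per-node
#'   vector.
#' @param variables subset of \code{c("u","u_tilde","v","v_tilde","w","q")}.
#' @return data.frame with columns \code{time, group, variable, value};
#'   \code{attr(, "ranking")} holds the groups ordered by terminal average
#'   toxic tau.
#' @export
summarize_trajectory <- function(traj, con, grouping = "region",
                                 variables = c("u_tilde", "v_tilde", "q")) {
  stopifnot(inherits(traj, "ad_trajectory"), inherits(con, "connectome"))
  N <- nrow(con$nodes)
  species <- c("u", "u_tilde", "v", "v_tilde", "w", "q")
  if (ncol(traj$states) != 6 * N)
    stop("trajectory does not match the connectome (expected 6N columns)")
  g <- if (length(grouping) == 1L && grouping %in% c("region", "brain_id"))
    con$nodes[[grouping]] else grouping
  if (length(g) != N) stop("`grouping` must have one entry per node")
  g <- factor(g)
  variables <- match.arg(variables, species, several.ok = TRUE)
  out <- list()
  for (v in variables) {
    k <- match(v, species)
    block <- traj$states[, ((k - 1L) * N + 1L):(k * N), drop = FALSE]
    means <- t(apply(block, 1L, function(row) tapply(row, g, mean)))
    if (nlevels(g) == 1L) means <- matrix(means, ncol = 1L,
                                          dimnames = list(NULL, levels(g)))
    out[[v]] <- data.frame(
      time = rep(traj$times, times = nlevels(g)),
      group = rep(levels(g), each = length(traj$times)),
      variable = v,
      value = as.vector(means))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  term <- res[res$variable == "v_tilde" & res$time == max(res$time), ]
  ranking <- if (nrow(term)) term$group[order(-term$value)] else levels(g)
  attr(res, "ranking") <- as.character(ranking)
  res
}
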