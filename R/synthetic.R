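#' Specification for the synthetic connectome generator
#'
#' Describes the brain-like random graphs the generator emulates.  Defaults
#' reproduce the summary statistics of the published whole-brain dataset:
#' edge density of about 16 edges per node, heavy-tailed fiber counts with
#' mean about 39.33 clipped to [1, 4966.5], and fiber lengths with mean about
#' 30.089 mm clipped to [10.270, 83.003] mm.  Region proportions default to
#' the relative sizes of the brain-ID catalogue (e.g. 12/49 basal ganglia,
#' 1/49 brain stem).
#'
#' @param n_nodes number of nodes (>= 2).
#' @param region_proportions named numeric vector over the seven regions,
#'   summing to 1.
#' @param edges_per_node target edge density E/N.
#' @param fiber_meanlog,fiber_sdlog log-normal parameters of the fiber-count
#'   distribution before clipping.
#' @param fiber_range clipping interval for fiber counts.
#' @param length_shape,length_scale gamma parameters of the fiber-length
#'   distribution (mm) before clipping.
#' @param length_range clipping interval for lengths (mm).
#' @param seed integer random seed (reproducibility contract: equal seeds
#'   give byte-identical node/edge tables).
#' @return An object of class \code{generator_spec}.
#' @export
generator_spec <- function(n_nodes = 200,
                           region_proportions = NULL,
                           edges_per_node = 16,
                           fiber_meanlog = log(39.33) - 1.4^2 / 2,
                           fiber_sdlog = 1.4,
                           fiber_range = c(1, 4966.5),
                           length_shape = 9,
                           length_scale = 30.089 / 9,
                           length_range = c(10.270, 83.003),
                           seed = 1L) {
  if (!is.numeric(n_nodes) || n_nodes < 2)
    stop("`n_nodes` must be at least 2")
  cat_map <- brain_id_catalogue()
  if (is.null(region_proportions)) {
    tab <- table(cat_map)
    region_proportions <- as.numeric(tab) / length(cat_map)
    names(region_proportions) <- names(tab)
  }
  unknown <- setdiff(names(region_proportions), unique(unname(cat_map)))
  if (length(unknown))
    stop("unknown region(s): ", paste(unknown, collapse = ", "))
  if (abs(sum(region_proportions) - 1) > 1e-8)
    stop("`region_proportions` must sum to 1")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (edges_per_node * n_nodes > max_edges)
    stop("infeasible edge density: ", edges_per_node * n_nodes,
         " edges requested but only ", max_edges, " pairs exist")
  structure(list(n_nodes = as.integer(n_nodes),
                 region_proportions = region_proportions,
                 edges_per_node = edges_per_node,
                 fiber_meanlog = fiber_meanlog, fiber_sdlog = fiber_sdlog,
                 fiber_range = fiber_range,
                 length_shape = length_shape, length_scale = length_scale,
                 length_range = length_range,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# coarse ellipsoidal layout: one Gaussian blob per region (cosmetic only;
# the dynamics depend solely on the edge fiber statistics)
region_centers <- function() {
  regions <- c("frontal", "parietal", "occipital", "temporal", "limbic",
               "basal ganglia", "brain stem")
  theta <- seq(0, 2 * pi, length.out = length(regions) + 1L)[-1L]
  data.frame(region = regions,
             x = 60 * cos(theta), y = 80 * sin(theta),
             z = c(40, 55, 35, 5, 15, 10, -20))
}

#' Generate a brain-like synthetic connectome
#'
#' Samples node positions as region-clustered Gaussian blobs on a coarse
#' ellipsoidal layout, assigns brain-ID labels from the per-region
#' catalogue, wires edges with a distance-decaying probability calibrated to
#' the target density (augmented to a connected graph if sampling leaves
#' isolated components), and draws fiber counts from a clipped log-normal and
#' lengths from a clipped gamma distribution.  Toxic seed sets are assigned
#' from the canonical seeding territories whenever the corresponding brain
#' IDs are present (guaranteed when the temporal/frontal and limbic regions
#' are populated).
#'
#' @param spec a [generator_spec()].
#' @return A [connectome()]; reproducible given \code{spec$seed}.
#' @examples
#' con <- generate_connectome(generator_spec(n_nodes = 60, seed = 7))
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_nodes
    cat_map <- brain_id_catalogue()
    regions <- names(spec$region_proportions)

    # multinomial region assignment, at least the rounded share each
    counts <- drop(stats::rmultinom(1, n, spec$region_proportions))
    region <- rep(regions, counts)
    centers <- region_centers()
    ci <- match(region, centers$region)
    x <- centers$x[ci] + stats::rnorm(n, 0, 12)
    y <- centers$y[ci] + stats::rnorm(n, 0, 12)
    z <- centers$z[ci] + stats::rnorm(n, 0, 10)
    brain_id <- vapply(region, function(r) {
      ids <- names(cat_map)[cat_map == r]
      ids[sample.int(length(ids), 1L)]
    }, character(1))

    # make sure the canonical seeding territories are populated when their
    # host regions are
    terr <- default_seed_brain_ids()
    if (!any(brain_id %in% terr$tau) && any(region == "limbic"))
      brain_id[which(region == "limbic")[1L]] <- "entorhinal"
    if (!any(brain_id %in% terr$abeta) && any(region == "temporal"))
      brain_id[which(region == "temporal")[1L]] <- "inferiortemporal"

    ids <- sprintf("n%04d", seq_len(n))
    nodes <- data.frame(id = ids, x = round(x, 3), y = round(y, 3),
                        z = round(z, 3), brain_id = brain_id,
                        region = region, stringsAsFactors = FALSE)

    # distance-decaying edge probabilities scaled to the target count
    pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    pair_j <- unlist(lapply(2:n, function(k) k:n))
    d <- sqrt((x[pair_i] - x[pair_j])^2 + (y[pair_i] - y[pair_j])^2 +
                (z[pair_i] - z[pair_j])^2)
    wts <- exp(-d / 30)
    target <- min(round(spec$edges_per_node * n), length(d))
    p <- pmin(1, wts * target / sum(wts))
    # renormalize for mass lost to capping
    for (it in 1:8) {
      deficit <- target - sum(p)
      if (abs(deficit) < 0.5) break
      free <- p < 1
      p[free] <- pmin(1, p[free] * (1 + deficit / sum(p[free])))
    }
    take <- stats::runif(length(d)) < p
    ei <- pair_i[take]; ej <- pair_j[take]

    # augment to a spanning structure: attach every component to component 1
    # through the geometrically closest cross pair
    comp <- components_of(n, ei, ej)
    while (length(unique(comp)) > 1L) {
      main <- which(comp == comp[1L])
      other_ids <- which(comp != comp[1L])
      other <- which(comp == comp[other_ids[1L]])
      dd <- outer(main, other, function(a, b)
        sqrt((x[a] - x[b])^2 + (y[a] - y[b])^2 + (z[a] - z[b])^2))
      k <- arrayInd(which.min(dd), dim(dd))
      a <- main[k[1L]]; b <- other[k[2L]]
      ei <- c(ei, min(a, b)); ej <- c(ej, max(a, b))
      comp <- components_of(n, ei, ej)
    }

    ord <- order(ei, ej)
    ei <- ei[ord]; ej <- ej[ord]
    m <- length(ei)
    n_fibers <- pmin(pmax(stats::rlnorm(m, spec$fiber_meanlog,
                                        spec$fiber_sdlog),
                          spec$fiber_range[1]), spec$fiber_range[2])
    length_mm <- pmin(pmax(stats::rgamma(m, shape = spec$length_shape,
                                         scale = spec$length_scale),
                           spec$length_range[1]), spec$length_range[2])
    edges <- data.frame(source = ids[ei], target = ids[ej],
                        n_fibers = round(n_fibers, 3),
                        length_mm = round(length_mm, 3),
                        stringsAsFactors = FALSE)
    connectome(nodes, edges)
  })
}

# connected components via label propagation (small graphs only)
components_of <- function(n, ei, ej) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_along(ei)) {
      a <- comp[ei[k]]; b <- comp[ej[k]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Catalogue of tiny hand-specified fixture graphs
#'
#' Deterministic miniature connectomes used by the oracle tests and the
#' worked examples:
#' \describe{
#'   \item{two_node}{one edge with n_fibers = 4, length_mm = 2, so the
#'     adjacency weight is exactly 1}
#'   \item{path3}{3-node path with unit weights (n = 1, l = 1)}
#'   \item{star5}{5-node star with unit weights}
#'   \item{toy12}{12 nodes in two regions (6 limbic with tau seed sites,
#'     6 frontal with amyloid seed sites), moderately weighted and fully
#'     connected}
#' }
#'
#' @return Named list of [connectome()] objects.
#' @export
fixture_graphs <- function() {
  mknodes <- function(ids, bids) {
    cat_map <- brain_id_catalogue()
    data.frame(id = ids, x = seq_along(ids) * 10, y = 0, z = 0,
               brain_id = bids, region = unname(cat_map[bids]),
               stringsAsFactors = FALSE)
  }
  two_node <- connectome(
    mknodes(c("n1", "n2"), c("entorhinal", "superiorfrontal")),
    data.frame(source = "n1", target = "n2", n_fibers = 4, length_mm = 2))
  path3 <- connectome(
    mknodes(c("n1", "n2", "n3"),
            c("entorhinal", "precuneus", "inferiortemporal")),
    data.frame(source = c("n1", "n2"), target = c("n2", "n3"),
               n_fibers = 1, length_mm = 1))
  star5 <- connectome(
    mknodes(c("n1", "n2", "n3", "n4", "n5"),
            c("precuneus", "entorhinal", "superiorfrontal", "cuneus",
              "inferiortemporal")),
    data.frame(source = "n1", target = c("n2", "n3", "n4", "n5"),
               n_fibers = 1, length_mm = 1))
  toy_bids <- c(rep("entorhinal", 3), rep("parahippocampal", 3),
                rep("frontalpole", 2), rep("superiorfrontal", 4))
  toy_ids <- sprintf("t%02d", 1:12)
  ring <- data.frame(source = toy_ids, target = toy_ids[c(2:12, 1)])
  cross <- data.frame(source = toy_ids[c(1, 3, 5, 7)],
                      target = toy_ids[c(7, 9, 11, 12)])
  toy_edges <- rbind(ring, cross)
  set_fibers <- c(35, 60, 22, 48, 31, 55, 27, 41, 38, 52, 29, 44,
                  33, 47, 25, 39)
  set_lengths <- c(18, 25, 31, 22, 27, 19, 24, 29, 21, 26, 23, 28,
                   35, 30, 33, 20)
  toy_edges$n_fibers <- set_fibers
  toy_edges$length_mm <- set_lengths
  toy12 <- connectome(mknodes(toy_ids, toy_bids), toy_edges)
  list(two_node = two_node, path3 = path3, star5 = star5, toy12 = toy12)
}
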