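#' Write a trajectory as tidy long-format CSV
#'
#' Fixed column order \code{time,node,variable,value}.  For local
#' trajectories the node column is \code{"local"}; for network trajectories
#' the node ids stored in the trajectory metadata are used.
#'
#' @param traj an \code{ad_trajectory}.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "ad_trajectory"))
  st <- traj$states
  if (!is.null(traj$meta$node_ids)) {
    N <- length(traj$meta$node_ids)
    species <- traj$meta$species
    node <- rep(rep(traj$meta$node_ids, each = length(traj$times)),
                times = length(species))
    variable <- rep(species, each = N * length(traj$times))
  } else {
    vars <- colnames(st)
    if (is.null(vars)) vars <- paste0("y", seq_len(ncol(st)))
    node <- "local"
    variable <- rep(vars, each = length(traj$times))
  }
  df <- data.frame(time = rep(traj$times, times = ncol(st)),
                   node = node,
                   variable = variable,
                   value = as.vector(st))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy trajectory CSV back into a long data frame
#'
#' @param path CSV written by [write_trajectory_csv()].
#' @return data.frame with columns \code{time, node, variable, value}.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "node", "variable", "value")
  if (!identical(names(df), need))
    stop("not a trajectory CSV (expected header time,node,variable,value)")
  df
}

#' Run manifest for reproducible execution
#'
#' Records the resolved configuration, package version, seeds, input file
#' checksums (MD5) and wall-clock metadata of a run; written next to the run
#' outputs as JSON.
#'
#' @param config named list of the resolved configuration.
#' @param seed the seed(s) used.
#' @param input_files character vector of input paths to checksum.
#' @param path optional JSON output path.
#' @return The manifest list (invisibly if written).
#' @export
run_manifest <- function(config, seed = NULL, input_files = character(0),
                         path = NULL) {
  sums <- if (length(input_files)) {
    as.list(tools::md5sum(input_files))
  } else list()
  man <- list(
    package = "fadnet",
    version = as.character(utils::packageVersion("fadnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_checksums = sums)
  if (is.null(path)) return(man)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(man)
}
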