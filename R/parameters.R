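#' Model parameters for the amyloid-beta / tau / astrocyte system
#'
#' Constructs the full parameter set of the five-variable temporal model, the
#' neuronal damage equation, and the per-species network diffusion
#' coefficients.  The defaults are the synthetic secondary-tauopathy set used
#' throughout the package.
#'
#' All quantities are nondimensional.  The fields are:
#' \describe{
#'   \item{a0, a1}{production and clearance rates of healthy amyloid-beta (u)}
#'   \item{a2}{healthy-to-toxic amyloid conversion rate (heterodimer term)}
#'   \item{a1_tilde}{clearance rate of toxic amyloid-beta (\eqn{\tilde u})}
#'   \item{b0, b1}{production and clearance rates of healthy tau (v)}
#'   \item{b2}{healthy-to-toxic tau conversion rate}
#'   \item{b1_tilde}{clearance rate of toxic tau (\eqn{\tilde v})}
#'   \item{b3}{amyloid-tau coupling (toxic amyloid catalyses tau conversion)}
#'   \item{c0, c1}{astrocyte production rate and carrying-capacity scale; the
#'     astrocyte density saturates at \code{c0 * c1}}
#'   \item{mu}{astrocyte-mediated clearance/exacerbation rate of toxic
#'     amyloid: clearance while \eqn{w > \tilde u}, amplification otherwise
#'     (the "dual role")}
#'   \item{k1, k2, k3, k4}{damage weights: toxic amyloid, toxic tau, their
#'     product, and damage self-amplification}
#'   \item{rho_u, rho_u_tilde, rho_v, rho_v_tilde}{network diffusion
#'     coefficients of the four mobile species}
#'   \item{alpha}{fractional order of the Caputo derivative, in (0, 1];
#'     \code{alpha = 1} is the memoryless (Markovian) limit}
#' }
#'
#' @param ... named overrides of any default field.
#' @return An object of class \code{ad_params} (a named list).
#' @examples
#' p <- ad_params()
#' p$b3
#' ad_params(mu = 0.3, c1 = 0.3)$mu
#' @export
ad_params <- function(...) {
  p <- list(
    a0 = 1.035, a1 = 1.38, a2 = 1.38, a1_tilde = 0.828,
    b0 = 0.69, b1 = 1.38, b2 = 1.035, b1_tilde = 0.552, b3 = 4.14,
    c0 = 1.0, c1 = 0.1, mu = 0.1,
    k1 = 0.0001, k2 = 0.01, k3 = 0.1, k4 = 0.001,
    rho_u = 1.38, rho_u_tilde = 0.138, rho_v = 1.38, rho_v_tilde = 0.014,
    alpha = 1
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  structure(p, class = "ad_params")
}

#' Validate a parameter set
#'
#' Checks the structural invariants of an \code{ad_params} object: all rates
#' finite and nonnegative, \code{c1 > 0}, and \code{alpha} in (0, 1].
#'
#' @param params an \code{ad_params} object (or coercible named list).
#' @return A character vector of violated invariants; \code{character(0)} when
#'   the set is valid.
#' @examples
#' validate_params(ad_params())          # character(0)
#' validate_params(ad_params(c1 = 0))    # flags c1
#' @export
validate_params <- function(params) {
  params <- as_ad_params(params)
  bad <- character(0)
  num <- vapply(params, function(x) is.numeric(x) && length(x) == 1L, logical(1))
  if (!all(num))
    return(paste0("non-scalar or non-numeric field(s): ",
                  paste(names(params)[!num], collapse = ", ")))
  vals <- unlist(params)
  if (any(!is.finite(vals)))
    bad <- c(bad, paste0("non-finite field(s): ",
                         paste(names(vals)[!is.finite(vals)], collapse = ", ")))
  rates <- setdiff(names(vals), "alpha")
  neg <- rates[is.finite(vals[rates]) & vals[rates] < 0]
  if (length(neg))
    bad <- c(bad, paste0("negative rate(s): ", paste(neg, collapse = ", ")))
  if (is.finite(params$c1) && params$c1 <= 0)
    bad <- c(bad, "c1 must be > 0 (astrocyte carrying capacity scale)")
  if (is.finite(params$alpha) && (params$alpha <= 0 || params$alpha > 1))
    bad <- c(bad, "alpha must lie in (0, 1]")
  bad
}

#' @export
print.ad_params <- function(x, ...) {
  cat("<ad_params>\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

as_ad_params <- function(params) {
  if (inherits(params, "ad_params")) return(params)
  if (is.list(params) && !is.null(names(params)))
    return(do.call(ad_params, params))
  stop("`params` must be an ad_params object or a named list")
}

stop_if_invalid <- function(params) {
  bad <- validate_params(params)
  if (length(bad))
    stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  invisible(params)
}

#' Read or write a parameter set as a flat YAML/JSON file
#'
#' Keys follow the field names of [ad_params()] (`a0`, `a1_tilde`, `b3`,
#' `mu`, `k1`, `rho_u`, `alpha`, ...).  The format is inferred from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @return `read_params` returns an `ad_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: ", ext))
  do.call(ad_params, as.list(vals))
}

#' @rdname read_params
#' @param params an `ad_params` object.
#' @export
write_params <- function(params, path) {
  params <- as_ad_params(params)
  ext <- tolower(tools::file_ext(path))
  vals <- lapply(unclass(params), identity)
  switch(ext,
    yaml = , yml = yaml::write_yaml(vals, path),
    json = jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: ", ext))
  invisible(path)
}
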