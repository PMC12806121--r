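#' Enumerate the nonnegative equilibria of the temporal model
#'
#' The five-variable system factorizes, so its equilibria can be enumerated by
#' a branch cascade rather than a blind multistart:
#' \itemize{
#'   \item \code{u}: either 0, or on the logistic branch
#'     \code{u = (a0 - a2*u_tilde)/a1};
#'   \item \code{u_tilde}: either 0, or the interior root of
#'     \code{a2 u - mu (w - u_tilde) = a1_tilde};
#'   \item \code{w}: either 0, or the astrocyte saturation \code{c0 * c1};
#'   \item \code{(v, v_tilde)}: \code{(0, 0)}, the tau-only logistic point
#'     \code{(b0/b1, 0)}, or the interior pair
#'     \code{v = b1_tilde / (b2 + b3 u_tilde)},
#'     \code{v_tilde = (b0 - b1 v) / (b2 + b3 u_tilde)}.
#' }
#' Each nonnegative candidate is polished by damped Newton iteration on the
#' analytic Jacobian and deduplicated.  Branch roots with negative or complex
#' components are excluded and reported in the \code{excluded} attribute.
#'
#' @param params an [ad_params()] object.
#' @param tol residual tolerance each returned point must satisfy (max norm).
#' @param dedup_tol points closer than this (max norm) are merged.
#' @return A list of equilibrium points, each a list with fields
#'   \code{state} (5-vector), \code{branch} (label of the cascade branch) and
#'   \code{residual}.  The excluded (negative-component) branch roots are
#'   attached as \code{attr(, "excluded")}.
#' @examples
#' eq <- find_equilibria(ad_params())
#' # contains the positive equilibrium near (0.596, 0.154, 0.33, 0.14, 0.1)
#' @export
find_equilibria <- function(params, tol = 1e-10, dedup_tol = 1e-8) {
  params <- stop_if_invalid(as_ad_params(params))
  p <- params

  # (u, u_tilde) branches given w
  ab_branches <- function(w) {
    br <- list(list(u = 0, ut = 0, lab = "u=0,ut=0"))
    br <- c(br, list(list(u = p$a0 / p$a1, ut = 0, lab = "u=a0/a1,ut=0")))
    if (p$mu > 0) {
      # u = 0 branch with toxic amyloid persisting: mu*ut = a1_tilde + mu*w
      br <- c(br, list(list(u = 0, ut = (p$a1_tilde + p$mu * w) / p$mu,
                            lab = "u=0,ut>0")))
    }
    den <- p$a2^2 / p$a1 - p$mu
    if (abs(den) > .Machine$double.eps^0.5) {
      ut <- (p$a2 * p$a0 / p$a1 - p$a1_tilde - p$mu * w) / den
      u <- (p$a0 - p$a2 * ut) / p$a1
      br <- c(br, list(list(u = u, ut = ut, lab = "interior-ab")))
    }
    br
  }
  # (v, v_tilde) branches given u_tilde
  tau_branches <- function(ut) {
    br <- list(list(v = 0, vt = 0, lab = "v=0,vt=0"),
               list(v = p$b0 / p$b1, vt = 0, lab = "v=b0/b1,vt=0"))
    s <- p$b2 + p$b3 * ut
    if (s > .Machine$double.eps^0.5) {
      v <- p$b1_tilde / s
      vt <- (p$b0 - p$b1 * v) / s
      br <- c(br, list(list(v = v, vt = vt, lab = "interior-tau")))
    }
    br
  }

  candidates <- list()
  for (w in unique(c(0, p$c0 * p$c1))) {
    for (ab in ab_branches(w)) {
      for (tv in tau_branches(ab$ut)) {
        lab <- paste0(ab$lab, ";", tv$lab, ";w=", format(w))
        candidates <- c(candidates, list(list(
          state = c(ab$u, ab$ut, tv$v, tv$vt, w), branch = lab)))
      }
    }
  }

  excluded <- list()
  points <- list()
  for (cand in candidates) {
    x <- cand$state
    if (any(!is.finite(x))) next
    if (any(x < -1e-12)) {
      excluded <- c(excluded, list(cand))
      next
    }
    x <- pmax(x, 0)
    x <- newton_polish(x, p)
    if (is.null(x) || any(x < -1e-9)) {
      excluded <- c(excluded, list(cand))
      next
    }
    x <- pmax(x, 0)
    res <- max(abs(rhs_local_(x, p)))
    if (!is.finite(res) || res > tol) next
    points <- c(points, list(list(state = x, branch = cand$branch,
                                  residual = res)))
  }

  # deduplicate
  keep <- list()
  for (pt in points) {
    dup <- any(vapply(keep, function(k)
      max(abs(k$state - pt$state)) < dedup_tol, logical(1)))
    if (!dup) keep <- c(keep, list(pt))
  }
  structure(keep, excluded = excluded, class = "ad_equilibria")
}

newton_polish <- function(x, p, maxit = 50L, tol = 1e-13) {
  for (i in seq_len(maxit)) {
    f <- rhs_local_(x, p)
    if (max(abs(f)) < tol) return(x)
    J <- jacobian_(x, p)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) {
      # singular Jacobian (degenerate branch): accept only if already converged
      return(if (max(abs(f)) < 1e-11) x else NULL)
    }
    x <- x - step
    if (any(!is.finite(x))) return(NULL)
  }
  if (max(abs(rhs_local_(x, p))) < 1e-11) x else NULL
}

#' @export
print.ad_equilibria <- function(x, ...) {
  cat("<ad_equilibria> ", length(x), " nonnegative equilibria\n", sep = "")
  for (pt in x) {
    cat(sprintf("  (%s)  residual %.2e  [%s]\n",
                paste(formatC(pt$state, digits = 6, format = "g"),
                      collapse = ", "),
                pt$residual, pt$branch))
  }
  invisible(x)
}

#' Analytic Jacobian of the temporal model
#'
#' Builds the 5x5 Jacobian of [rhs_local()] at a point from the closed-form
#' entries (the amyloid block is upper-triangular-coupled to the astrocyte
#' column; the tau block couples to toxic amyloid; the astrocyte row is
#' decoupled).
#'
#' @param state numeric 5-vector \code{(u, u_tilde, v, v_tilde, w)}.
#' @param params an [ad_params()] object.
#' @return A 5x5 numeric matrix.
#' @export
ad_jacobian <- function(state, params) {
  params <- stop_if_invalid(as_ad_params(params))
  if (!is.numeric(state) || length(state) != 5L || any(!is.finite(state)))
    stop("`state` must be a finite numeric 5-vector")
  jacobian_(state, params)
}

jacobian_ <- function(s, p) {
  u <- s[[1L]]; ut <- s[[2L]]; v <- s[[3L]]; vt <- s[[4L]]; w <- s[[5L]]
  J <- matrix(0, 5, 5)
  J[1, 1] <- p$a0 - 2 * p$a1 * u - p$a2 * ut
  J[1, 2] <- -p$a2 * u
  J[2, 1] <- p$a2 * ut
  J[2, 2] <- -p$a1_tilde + p$a2 * u - p$mu * (w - 2 * ut)
  J[2, 5] <- -p$mu * ut
  J[3, 2] <- -p$b3 * v * vt
  J[3, 3] <- p$b0 - 2 * p$b1 * v - p$b2 * vt - p$b3 * ut * vt
  J[3, 4] <- -p$b2 * v - p$b3 * ut * v
  J[4, 2] <- p$b3 * v * vt
  J[4, 3] <- p$b2 * vt + p$b3 * ut * vt
  J[4, 4] <- -p$b1_tilde + p$b2 * v + p$b3 * ut * v
  J[5, 5] <- p$c0 - 2 * w / p$c1
  J
}

#' Classify local stability of an equilibrium, integer or fractional order
#'
#' For \code{alpha = 1} the point is locally asymptotically stable iff all
#' Jacobian eigenvalues have negative real part.  For \code{0 < alpha < 1} the
#' Matignon-type condition applies: stable iff every eigenvalue satisfies
#' \code{|arg(lambda)| > alpha * pi / 2}.  The stability margin is
#' \code{-max(Re(lambda))} (integer order) or
#' \code{min(|arg(lambda)|) - alpha*pi/2} (fractional).  Margins within
#' \code{marginal_tol} of zero are reported as marginal, not stable.
#'
#' @param point a 5-vector, or an equilibrium entry from [find_equilibria()].
#' @param params an [ad_params()] object.
#' @param alpha fractional order in (0, 1]; defaults to \code{params$alpha}.
#' @param marginal_tol half-width of the marginal band around zero margin.
#' @return A list of class \code{stability_verdict}: \code{eigenvalues}
#'   (complex 5-vector), \code{stable}, \code{marginal}, \code{criterion}
#'   (\code{"real-part"} or \code{"argument"}), and \code{margin}.
#' @examples
#' eq <- find_equilibria(ad_params())
#' classify_stability(eq[[1]], ad_params(), alpha = 0.8)
#' @export
classify_stability <- function(point, params, alpha = NULL,
                               marginal_tol = 1e-9) {
  params <- stop_if_invalid(as_ad_params(params))
  if (is.null(alpha)) alpha <- params$alpha
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  state <- if (is.list(point)) point$state else point
  if (!is.numeric(state) || length(state) != 5L)
    stop("`point` must be a 5-vector or an equilibrium entry")
  J <- jacobian_(state, params)
  ev <- eigen(J, only.values = TRUE)$values
  if (any(!is.finite(Re(ev))) || any(!is.finite(Im(ev))))
    stop("eigenproblem returned non-finite eigenvalues")
  if (alpha == 1) {
    margin <- -max(Re(ev))
    criterion <- "real-part"
  } else {
    margin <- min(abs(Arg(ev))) - alpha * pi / 2
    criterion <- "argument"
  }
  marginal <- abs(margin) <= marginal_tol
  structure(list(eigenvalues = ev,
                 stable = !marginal && margin > 0,
                 marginal = marginal,
                 criterion = criterion,
                 margin = margin,
                 alpha = alpha),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("<stability_verdict> %s (criterion: %s, alpha = %g, margin = %.3e)\n",
              if (x$marginal) "marginal" else if (x$stable) "stable" else "unstable",
              x$criterion, x$alpha, x$margin))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify a parameter set as primary or secondary tauopathy
#'
#' Toxic tau is self-sustaining ("primary tauopathy") when it can invade the
#' tau-only subsystem at the healthy carrying capacity without any amyloid
#' coupling, i.e. when \code{b2 * b0 / b1 > b1_tilde}.  Otherwise toxic tau
#' requires the amyloid coupling \code{b3} to persist ("secondary
#' tauopathy").  The boundary case is classified as secondary.
#'
#' @param params an [ad_params()] object (requires \code{b1 > 0}).
#' @return \code{"primary"} or \code{"secondary"}.
#' @examples
#' classify_tauopathy(ad_params())            # "secondary"
#' classify_tauopathy(ad_params(b2 = 1.6))    # "primary"
#' @export
classify_tauopathy <- function(params) {
  params <- stop_if_invalid(as_ad_params(params))
  if (params$b1 <= 0)
    stop("classify_tauopathy requires b1 > 0 (healthy tau carrying capacity)")
  if (params$b2 * params$b0 / params$b1 > params$b1_tilde) "primary"
  else "secondary"
}

#' Export equilibria and their stability verdicts as JSON
#'
#' @param equilibria result of [find_equilibria()].
#' @param params the parameter set used.
#' @param alpha fractional order used for classification.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
equilibria_to_json <- function(equilibria, params, alpha = 1, path = NULL) {
  recs <- lapply(equilibria, function(pt) {
    v <- classify_stability(pt, params, alpha = alpha)
    list(state = pt$state,
         branch = pt$branch,
         residual = pt$residual,
         eigenvalues = lapply(v$eigenvalues,
                              function(z) c(Re(z), Im(z))),
         criterion = v$criterion,
         margin = v$margin,
         stable = v$stable)
  })
  js <- jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
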