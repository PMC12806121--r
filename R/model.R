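#' Right-hand side of the five-variable temporal model
#'
#' Evaluates the time-derivatives of the coupled healthy/toxic amyloid-beta
#' (u, \eqn{\tilde u}), healthy/toxic tau (v, \eqn{\tilde v}) and astrocyte
#' (w) system:
#' \deqn{u_t = u(a_0 - a_1 u) - a_2 u\tilde u}
#' \deqn{\tilde u_t = -\tilde a_1\tilde u + a_2 u\tilde u - \mu\tilde u(w - \tilde u)}
#' \deqn{v_t = v(b_0 - b_1 v) - b_2 v\tilde v - b_3\tilde u v\tilde v}
#' \deqn{\tilde v_t = -\tilde b_1\tilde v + b_2 v\tilde v + b_3\tilde u v\tilde v}
#' \deqn{w_t = w(c_0 - w/c_1)}
#'
#' The same right-hand side is used for the Caputo fractional system; only the
#' time operator changes.
#'
#' @param state numeric 5-vector \code{(u, u_tilde, v, v_tilde, w)}.
#' @param params an [ad_params()] object.
#' @return Numeric 5-vector of derivatives, in the same order.
#' @examples
#' rhs_local(c(0.596, 0.154, 0.33, 0.14, 0.1), ad_params())  # ~ 0 (equilibrium)
#' @export
rhs_local <- function(state, params) {
  params <- stop_if_invalid(as_ad_params(params))
  if (!is.numeric(state) || length(state) != 5L)
    stop("`state` must be a numeric 5-vector (u, u_tilde, v, v_tilde, w)")
  if (any(!is.finite(state)))
    stop("`state` contains non-finite components")
  rhs_local_(state, params)
}

# internal, unvalidated version used in solver loops
rhs_local_ <- function(state, p) {
  u <- state[[1L]]; ut <- state[[2L]]; v <- state[[3L]]
  vt <- state[[4L]]; w <- state[[5L]]
  c(u * (p$a0 - p$a1 * u) - p$a2 * u * ut,
    -p$a1_tilde * ut + p$a2 * u * ut - p$mu * ut * (w - ut),
    v * (p$b0 - p$b1 * v) - p$b2 * v * vt - p$b3 * ut * v * vt,
    -p$b1_tilde * vt + p$b2 * v * vt + p$b3 * ut * v * vt,
    w * (p$c0 - w / p$c1))
}

#' Right-hand side of the neuronal damage equation
#'
#' Damage accumulates from the local toxic loads and from itself,
#' \deqn{q_t = (1 - q)(k_1\tilde u + k_2\tilde v + k_3\tilde u\tilde v + k_4 q),}
#' so that q is nondecreasing for nonnegative toxic input and saturates at
#' q = 1 (the nonfunctional state).  q = 0 is the healthy state.
#'
#' @param q damage fraction in [0, 1].
#' @param u_tilde,v_tilde nonnegative toxic amyloid-beta and tau loads.
#' @param params an [ad_params()] object.
#' @return Scalar derivative, nonnegative under the stated preconditions.
#' @examples
#' rhs_damage(0, 0.154, 0.14, ad_params())
#' @export
rhs_damage <- function(q, u_tilde, v_tilde, params) {
  params <- stop_if_invalid(as_ad_params(params))
  if (!is.numeric(q) || any(!is.finite(q)) || any(q < 0) || any(q > 1))
    stop("`q` must lie in [0, 1]")
  if (any(!is.finite(u_tilde)) || any(!is.finite(v_tilde)) ||
      any(u_tilde < 0) || any(v_tilde < 0))
    stop("toxic loads must be finite and nonnegative")
  (1 - q) * (params$k1 * u_tilde + params$k2 * v_tilde +
               params$k3 * u_tilde * v_tilde + params$k4 * q)
}
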