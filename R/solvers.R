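#' Classical fourth-order Runge-Kutta integration
#'
#' Fixed-step RK4 for an autonomous system \code{y' = rhs(y)}.  This is the
#' reference integrator for the memoryless (\code{alpha = 1}) model; the
#' model-specific fast paths in [simulate_local()] and [simulate_network()]
#' are cross-checked against it.
#'
#' @param rhs function of one argument (the state vector) returning the
#'   derivative vector.
#' @param y0 numeric initial state.
#' @param t_end final time (> 0).
#' @param dt step size (> 0); the last step is shortened to land on `t_end`.
#' @return An \code{ad_trajectory}: list with \code{times} (length M+1),
#'   \code{states} ((M+1) x d matrix) and \code{meta} (alpha, dt, solver).
#' @examples
#' tr <- solve_rk4(function(y) -y, 1, t_end = 1, dt = 0.01)
#' tail(tr$states, 1)  # exp(-1)
#' @export
solve_rk4 <- function(rhs, y0, t_end, dt = 0.01) {
  check_grid(t_end, dt)
  y <- as.numeric(y0)
  d <- length(y)
  times <- time_grid(t_end, dt)
  M <- length(times) - 1L
  out <- matrix(NA_real_, M + 1L, d)
  out[1L, ] <- y
  for (n in seq_len(M)) {
    h <- times[n + 1L] - times[n]
    k1 <- rhs(y)
    k2 <- rhs(y + h / 2 * k1)
    k3 <- rhs(y + h / 2 * k2)
    k4 <- rhs(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)))
      stop(sprintf("solution blew up (non-finite state) at t = %g; last finite time %g",
                   times[n + 1L], times[n]))
    out[n + 1L, ] <- y
  }
  new_trajectory(times, out, alpha = 1, dt = dt, solver = "rk4")
}

#' Adams-Bashforth-Moulton predictor-corrector for Caputo systems
#'
#' Solves \code{D^alpha y = rhs(y)} (Caputo derivative of order
#' \code{0 < alpha <= 1}, initial condition at t = 0, no pre-history) on a
#' uniform grid with the fractional Adams scheme: an Adams-Bashforth predictor
#' with convolution weights \code{(n+1-j)^alpha - (n-j)^alpha} followed by one
#' Adams-Moulton corrector pass with weights
#' \code{(n-j+2)^(alpha+1) + (n-j)^(alpha+1) - 2(n-j+1)^(alpha+1)}.  The full
#' history is retained (no kernel truncation), so the cost is O(M^2) in the
#' number of steps M.  \code{alpha = 1} dispatches to [solve_rk4()].
#'
#' @inheritParams solve_rk4
#' @param alpha fractional order in (0, 1].
#' @return An \code{ad_trajectory} (see [solve_rk4()]).
#' @examples
#' tr <- solve_caputo_pc(function(y) -y, 1, alpha = 0.8, t_end = 1, dt = 0.01)
#' mittag_leffler(0.8, -1)  # reference value for the endpoint
#' @export
solve_caputo_pc <- function(rhs, y0, alpha, t_end, dt = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (alpha == 1) {
    tr <- solve_rk4(rhs, y0, t_end, dt)
    tr$meta$alpha <- 1
    return(tr)
  }
  check_grid(t_end, dt)
  times <- time_grid(t_end, dt)
  if (!isTRUE(all.equal(diff(times), rep(dt, length(times) - 1L),
                        tolerance = 1e-10)))
    stop("the Caputo predictor-corrector requires t_end to be a multiple of dt")
  y0 <- as.numeric(y0)
  d <- length(y0)
  M <- length(times) - 1L

  kb <- caputo_kernel_b(alpha, M)   # kb[k+1] = (k+1)^a - k^a
  kc <- caputo_kernel_c(alpha, M)   # kc[k+1] = (k+2)^(a+1)+k^(a+1)-2(k+1)^(a+1)
  g1 <- gamma(alpha + 1)
  g2 <- gamma(alpha + 2)
  ha1 <- dt^alpha / g1
  ha2 <- dt^alpha / g2

  F <- matrix(NA_real_, M + 1L, d)  # rhs history
  Y <- matrix(NA_real_, M + 1L, d)
  Y[1L, ] <- y0
  F[1L, ] <- rhs(y0)
  for (n in 0:(M - 1L)) {
    j <- 0:n
    wb <- kb[n - j + 1L]
    # predictor
    sp <- crossprod(F[j + 1L, , drop = FALSE], wb)[, 1L]
    yp <- y0 + ha1 * sp
    fp <- rhs(yp)
    # corrector: a_{0,n+1} explicit, a_{j,n+1} = kc[n-j] for 1 <= j <= n
    a0 <- n^(alpha + 1) - (n - alpha) * (n + 1)^alpha
    wa <- c(a0, if (n >= 1L) kc[n - seq_len(n) + 1L])
    sc <- crossprod(F[j + 1L, , drop = FALSE], wa)[, 1L]
    ynew <- y0 + ha2 * (fp + sc)
    if (any(!is.finite(ynew)))
      stop(sprintf("solution blew up (non-finite state) at t = %g; last finite time %g",
                   times[n + 2L], times[n + 1L]))
    Y[n + 2L, ] <- ynew
    F[n + 2L, ] <- rhs(ynew)
  }
  new_trajectory(times, Y, alpha = alpha, dt = dt, solver = "caputo-abm-pece")
}

caputo_kernel_b <- function(alpha, M) {
  k <- 0:M
  (k + 1)^alpha - k^alpha
}

caputo_kernel_c <- function(alpha, M) {
  k <- 0:M
  (k + 2)^(alpha + 1) + k^(alpha + 1) - 2 * (k + 1)^(alpha + 1)
}

#' Mittag-Leffler function E_alpha(z)
#'
#' Series evaluation \eqn{E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k + 1)}
#' summed until the terms fall below machine precision relative to the
#' accumulated sum.  Serves as the closed-form oracle for the linear Caputo
#' relaxation problem \code{D^alpha y = -y}, whose solution is
#' \code{E_alpha(-t^alpha)}.  For \code{alpha = 1} this is \code{exp(z)}.
#'
#' @param alpha order in (0, 1].
#' @param z real argument with moderate magnitude (|z| <= 10; the plain
#'   series is numerically unreliable beyond).
#' @return E_alpha(z) as a scalar.
#' @examples
#' mittag_leffler(1, -1)          # exp(-1)
#' mittag_leffler(0.5, -1)        # equals exp(1) * erfc(1)
#' @export
mittag_leffler <- function(alpha, z) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("`alpha` must lie in (0, 1]")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("`z` must be a finite scalar")
  if (abs(z) > 10)
    stop("|z| > 10: plain series evaluation is outside its reliable domain")
  if (alpha == 1) return(exp(z))
  s <- 0
  term_max <- 0
  for (k in 0:2000) {
    term <- z^k / gamma(alpha * k + 1)
    s <- s + term
    term_max <- max(term_max, abs(term))
    if (k > 5 && abs(term) < .Machine$double.eps * max(1, abs(s)))
      return(s)
  }
  stop("Mittag-Leffler series did not converge (divergent tail detected)")
}

# ---- trajectory container ---------------------------------------------------

new_trajectory <- function(times, states, alpha, dt, solver, extra = list()) {
  structure(c(list(times = times, states = states,
                   meta = c(list(alpha = alpha, dt = dt, solver = solver),
                            extra))),
            class = "ad_trajectory")
}

#' @export
print.ad_trajectory <- function(x, ...) {
  cat(sprintf("<ad_trajectory> %d time points on [0, %g], %d state(s), solver %s (alpha = %g)\n",
              length(x$times), max(x$times), ncol(x$states),
              x$meta$solver, x$meta$alpha))
  invisible(x)
}

time_grid <- function(t_end, dt) {
  M <- floor(t_end / dt + 1e-9)
  times <- dt * (0:M)
  if (t_end - times[M + 1L] > 1e-9 * max(1, t_end))
    times <- c(times, t_end)
  times
}

check_grid <- function(t_end, dt) {
  if (!is.numeric(t_end) || length(t_end) != 1L || !is.finite(t_end) || t_end <= 0)
    stop("`t_end` must be a positive finite scalar")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a positive finite scalar")
  if (dt > t_end) stop("`dt` must not exceed `t_end`")
  invisible(TRUE)
}
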