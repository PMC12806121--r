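#' Uniform parameter samples around a nominal set
#'
#' Draws each selected parameter independently and uniformly from
#' \code{[p(1-d), p(1+d)]} around its nominal value p with deviation
#' fraction d.  By default the 16 local reaction/damage parameters are
#' sampled (the network diffusivities play no role in the temporal model the
#' sensitivity analysis evaluates).
#'
#' @param nominal an [ad_params()] object.
#' @param n number of samples (>= 3).
#' @param deviation deviation fraction in (0, 1); \code{deviation = 0} is
#'   allowed and returns constant columns.
#' @param seed optional integer seed (sampling is reproducible given it).
#' @param param_names which parameters to sample.
#' @return n x p numeric matrix with parameter names as column names.
#' @export
sample_parameters <- function(nominal, n = 1000, deviation = 0.10,
                              seed = NULL, param_names = local_param_names) {
  nominal <- stop_if_invalid(as_ad_params(nominal))
  if (!is.numeric(n) || n < 3)
    stop("`n` must be at least 3 (correlation undefined below)")
  if (!is.numeric(deviation) || deviation < 0 || deviation >= 1)
    stop("`deviation` must lie in [0, 1)")
  unknown <- setdiff(param_names, names(nominal))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  draw <- function() {
    vals <- unlist(nominal[param_names])
    lo <- vals * (1 - deviation)
    hi <- vals * (1 + deviation)
    M <- matrix(stats::runif(n * length(vals)), nrow = n)
    M <- sweep(sweep(M, 2, hi - lo, `*`), 2, lo, `+`)
    colnames(M) <- param_names
    M
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Pearson product-moment correlation
#'
#' Standard sample correlation of two equal-length vectors.  When either
#' vector has zero variance the coefficient is undefined and \code{NA} is
#' returned (with a \code{"zero-variance"} attribute) rather than a silent
#' value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation coefficient in [-1, 1], or NA for degenerate input.
#' @examples
#' pearson(c(1, 2, 3), c(2, 4, 6))   # 1
#' pearson(c(1, 2, 3), c(1, 3, 2))   # 0.5
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(structure(NA_real_, reason = "zero-variance"))
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sx * sy)
}

#' Global sensitivity analysis of the temporal model
#'
#' Implements the uniform-sampling Pearson procedure: n parameter sets are
#' drawn within +/- deviation of the nominal values, the memoryless
#' (\code{alpha = 1}) temporal model with damage is integrated by RK4 from a
#' fixed initial condition to \code{t_eval}, and each sampled parameter is
#' correlated against each of the six outputs
#' \code{(u, u_tilde, v, v_tilde, w, q)} evaluated at \code{t_eval}.
#'
#' The default initial condition places the system near the disease-free
#' state with a 1% toxic perturbation:
#' u = 0.75, \eqn{\tilde u} = 0.0075, v = 0.5, \eqn{\tilde v} = 0.005,
#' w = 0.1, q = 0.
#'
#' @param nominal an [ad_params()] object.
#' @param n number of samples.
#' @param deviation deviation fraction.
#' @param t_eval evaluation time.
#' @param dt RK4 step.
#' @param seed integer seed for the sampling.
#' @param init initial \code{(u, u_tilde, v, v_tilde, w)}.
#' @param q0 initial damage.
#' @param param_names parameters to sample (default: the 16 local ones).
#' @return An object of class \code{sensitivity_result}: list with
#'   \code{samples} (n x p), \code{outputs} (n x 6), \code{correlations}
#'   (p x 6), \code{n_failed} (count of excluded blow-ups), and the run
#'   configuration.
#' @export
run_sensitivity <- function(nominal, n = 1000, deviation = 0.10,
                            t_eval = 200, dt = 0.01, seed = NULL,
                            init = c(0.75, 0.0075, 0.5, 0.005, 0.1),
                            q0 = 0, param_names = local_param_names) {
  nominal <- stop_if_invalid(as_ad_params(nominal))
  samples <- sample_parameters(nominal, n = n, deviation = deviation,
                               seed = seed, param_names = param_names)
  outs <- matrix(NA_real_, nrow(samples), 6,
                 dimnames = list(NULL, c("u", "u_tilde", "v", "v_tilde",
                                         "w", "q")))
  full0 <- c(init, q0)
  base_vec <- unlist(nominal[local_param_names])
  failed <- 0L
  for (i in seq_len(nrow(samples))) {
    pv <- base_vec
    pv[colnames(samples)] <- samples[i, ]
    res <- tryCatch(
      cpp_local_rk4(full0, pv, t_eval, dt, as.integer(round(t_eval / dt))),
      error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      next
    }
    outs[i, ] <- res$states[nrow(res$states), ]
  }
  ok <- stats::complete.cases(outs)
  cors <- matrix(NA_real_, ncol(samples), 6,
                 dimnames = list(colnames(samples), colnames(outs)))
  for (pn in colnames(samples))
    for (on in colnames(outs))
      cors[pn, on] <- pearson(samples[ok, pn], outs[ok, on])
  structure(list(samples = samples, outputs = outs, correlations = cors,
                 n_samples = nrow(samples), n_failed = failed,
                 deviation = deviation, t_eval = t_eval, dt = dt,
                 seed = seed, nominal = nominal),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> %d samples, +/-%g%% deviation, t_eval = %g (%d excluded)\n",
              x$n_samples, 100 * x$deviation, x$t_eval, x$n_failed))
  print(round(x$correlations, 3))
  invisible(x)
}
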