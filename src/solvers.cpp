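// Fast integrators for the amyloid/tau/astrocyte model:
//  - RK4 and Caputo Adams-Bashforth-Moulton (PECE, full memory) drivers
//  - local 6-state system (u, ut, v, vt, w, q)
//  - network 6N-state system with per-node parameters and per-species
//    Laplacian diffusion
//  - driven damage equation (toxic loads held fixed)
// The Caputo scheme matches the pure-R reference in solve_caputo_pc().

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::vec;
using arma::mat;

// parameter column order, shared with R/params_matrix()
enum Par { A0, A1, A2, A1T, B0, B1, B2, B1T, B3, C0, C1, MU,
           K1, K2, K3, K4, NPAR };

typedef std::function<vec(const vec&)> RhsFun;

static void local_rhs(const vec& y, const vec& p, vec& f) {
  const double u = y[0], ut = y[1], v = y[2], vt = y[3], w = y[4], q = y[5];
  f[0] = u * (p[A0] - p[A1] * u) - p[A2] * u * ut;
  f[1] = -p[A1T] * ut + p[A2] * u * ut - p[MU] * ut * (w - ut);
  f[2] = v * (p[B0] - p[B1] * v) - p[B2] * v * vt - p[B3] * ut * v * vt;
  f[3] = -p[B1T] * vt + p[B2] * v * vt + p[B3] * ut * v * vt;
  f[4] = w * (p[C0] - w / p[C1]);
  f[5] = (1.0 - q) * (p[K1] * ut + p[K2] * vt + p[K3] * ut * vt + p[K4] * q);
}

struct NetworkSystem {
  // P: N x NPAR per-node parameters; L*: N x N Laplacians (rho included)
  mat P;
  mat Lu, Lut, Lv, Lvt;
  arma::uword N;

  vec operator()(const vec& y) const {
    const vec u  = y.subvec(0, N - 1);
    const vec ut = y.subvec(N, 2 * N - 1);
    const vec v  = y.subvec(2 * N, 3 * N - 1);
    const vec vt = y.subvec(3 * N, 4 * N - 1);
    const vec w  = y.subvec(4 * N, 5 * N - 1);
    const vec q  = y.subvec(5 * N, 6 * N - 1);
    vec f(6 * N);
    f.subvec(0, N - 1) =
      u % (P.col(A0) - P.col(A1) % u) - P.col(A2) % u % ut - Lu * u;
    f.subvec(N, 2 * N - 1) =
      -P.col(A1T) % ut + P.col(A2) % u % ut - P.col(MU) % ut % (w - ut)
      - Lut * ut;
    f.subvec(2 * N, 3 * N - 1) =
      v % (P.col(B0) - P.col(B1) % v) - P.col(B2) % v % vt
      - P.col(B3) % ut % v % vt - Lv * v;
    f.subvec(3 * N, 4 * N - 1) =
      -P.col(B1T) % vt + P.col(B2) % v % vt + P.col(B3) % ut % v % vt
      - Lvt * vt;
    f.subvec(4 * N, 5 * N - 1) = w % (P.col(C0) - w / P.col(C1));
    f.subvec(5 * N, 6 * N - 1) =
      (1.0 - q) % (P.col(K1) % ut + P.col(K2) % vt + P.col(K3) % ut % vt
                   + P.col(K4) % q);
    return f;
  }
};

static Rcpp::List run_rk4(const RhsFun& rhs, const vec& y0, double t_end,
                          double dt, int thin) {
  const arma::uword M = (arma::uword)std::floor(t_end / dt + 1e-9);
  const arma::uword nstore = M / thin + 1;
  vec y = y0;
  mat out(nstore, y0.n_elem);
  vec times(nstore);
  out.row(0) = y.t();
  times[0] = 0.0;
  arma::uword s = 1;
  for (arma::uword n = 0; n < M; ++n) {
    const vec k1 = rhs(y);
    const vec k2 = rhs(y + 0.5 * dt * k1);
    const vec k3 = rhs(y + 0.5 * dt * k2);
    const vec k4 = rhs(y + dt * k3);
    y += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!y.is_finite())
      Rcpp::stop("solution blew up (non-finite state) at t = %g; last finite time %g",
                 (n + 1) * dt, n * dt);
    if ((n + 1) % thin == 0) {
      out.row(s) = y.t();
      times[s] = (n + 1) * dt;
      ++s;
    }
  }
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("states") = out);
}

// Caputo ABM predictor-corrector, one corrector pass, full memory.
// F history kept column-major (dim x (M+1)) so each convolution is one gemm.
static Rcpp::List run_caputo(const RhsFun& rhs, const vec& y0, double alpha,
                             double t_end, double dt, int thin) {
  const arma::uword M = (arma::uword)std::floor(t_end / dt + 1e-9);
  const arma::uword d = y0.n_elem;
  const double ha1 = std::pow(dt, alpha) / std::tgamma(alpha + 1.0);
  const double ha2 = std::pow(dt, alpha) / std::tgamma(alpha + 2.0);

  // kernels in elapsed-step index k = n - j, stored reversed so that the
  // per-step weight vector (k = n..0) is a contiguous subvector and each
  // convolution is a single gemv over the history matrix
  vec kbrev(M + 1), kcrev(M + 1);
  for (arma::uword k = 0; k <= M; ++k) {
    kbrev[M - k] = std::pow((double)k + 1.0, alpha)
                 - std::pow((double)k, alpha);
    kcrev[M - k] = std::pow((double)k + 2.0, alpha + 1.0)
                 + std::pow((double)k, alpha + 1.0)
                 - 2.0 * std::pow((double)k + 1.0, alpha + 1.0);
  }

  mat F(d, M + 1);
  F.col(0) = rhs(y0);

  const arma::uword nstore = M / thin + 1;
  mat out(nstore, d);
  vec times(nstore);
  out.row(0) = y0.t();
  times[0] = 0.0;
  arma::uword s = 1;

  for (arma::uword n = 0; n < M; ++n) {
    // predictor weights for j = 0..n are kb[n-j] = kbrev[M-n+j]
    const vec sp = F.cols(0, n) * kbrev.subvec(M - n, M);
    const vec yp = y0 + ha1 * sp;
    const vec fp = rhs(yp);
    // corrector: a_{j,n+1} = kc[n-j] for j >= 1; a_{0,n+1} is special
    const double a0w = std::pow((double)n, alpha + 1.0)
      - ((double)n - alpha) * std::pow((double)n + 1.0, alpha);
    vec sc = F.cols(0, n) * kcrev.subvec(M - n, M);
    sc += (a0w - kcrev[M - n]) * F.col(0);
    const vec ynew = y0 + ha2 * (fp + sc);
    if (!ynew.is_finite())
      Rcpp::stop("solution blew up (non-finite state) at t = %g; last finite time %g",
                 (n + 1) * dt, n * dt);
    F.col(n + 1) = rhs(ynew);
    if ((n + 1) % thin == 0) {
      out.row(s) = ynew.t();
      times[s] = (n + 1) * dt;
      ++s;
    }
  }
  return Rcpp::List::create(Rcpp::Named("times") = times,
                            Rcpp::Named("states") = out);
}

// [[Rcpp::export]]
Rcpp::List cpp_local_rk4(const arma::vec& y0, const arma::vec& pars,
                         double t_end, double dt, int thin) {
  RhsFun rhs = [&](const vec& y) { vec f(6); local_rhs(y, pars, f); return f; };
  return run_rk4(rhs, y0, t_end, dt, thin);
}

// [[Rcpp::export]]
Rcpp::List cpp_local_caputo(const arma::vec& y0, const arma::vec& pars,
                            double alpha, double t_end, double dt, int thin) {
  RhsFun rhs = [&](const vec& y) { vec f(6); local_rhs(y, pars, f); return f; };
  return run_caputo(rhs, y0, alpha, t_end, dt, thin);
}

// [[Rcpp::export]]
Rcpp::List cpp_network_rk4(const arma::vec& y0, const arma::mat& P,
                           const arma::mat& Lu, const arma::mat& Lut,
                           const arma::mat& Lv, const arma::mat& Lvt,
                           double t_end, double dt, int thin) {
  NetworkSystem sys{P, Lu, Lut, Lv, Lvt, P.n_rows};
  RhsFun rhs = [&](const vec& y) { return sys(y); };
  return run_rk4(rhs, y0, t_end, dt, thin);
}

// [[Rcpp::export]]
Rcpp::List cpp_network_caputo(const arma::vec& y0, const arma::mat& P,
                              const arma::mat& Lu, const arma::mat& Lut,
                              const arma::mat& Lv, const arma::mat& Lvt,
                              double alpha, double t_end, double dt, int thin) {
  NetworkSystem sys{P, Lu, Lut, Lv, Lvt, P.n_rows};
  RhsFun rhs = [&](const vec& y) { return sys(y); };
  return run_caputo(rhs, y0, alpha, t_end, dt, thin);
}

// damage equation with toxic loads held fixed at (ut, vt)
// [[Rcpp::export]]
Rcpp::List cpp_damage_driven(double q0, double ut, double vt,
                             const arma::vec& pars, double alpha,
                             double t_end, double dt, int thin) {
  const double drive = pars[K1] * ut + pars[K2] * vt + pars[K3] * ut * vt;
  const double k4 = pars[K4];
  RhsFun rhs = [&](const vec& y) {
    vec f(1);
    f[0] = (1.0 - y[0]) * (drive + k4 * y[0]);
    return f;
  };
  vec y0(1);
  y0[0] = q0;
  if (alpha >= 1.0) return run_rk4(rhs, y0, t_end, dt, thin);
  return run_caputo(rhs, y0, alpha, t_end, dt, thin);
}

// RK4 and Caputo drivers for an arbitrary R-level vector field; used by the
// sensitivity module's one-at-a-time controls and by tests.
// [[Rcpp::export]]
Rcpp::List cpp_generic_caputo(Rcpp::Function rhs, const arma::vec& y0,
                              double alpha, double t_end, double dt, int thin) {
  RhsFun f = [&](const vec& y) {
    return Rcpp::as<vec>(rhs(Rcpp::NumericVector(y.begin(), y.end())));
  };
  return run_caputo(f, y0, alpha, t_end, dt, thin);
}
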