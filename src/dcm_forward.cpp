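// Fixed-step RK4 integration of the bilinear neurodynamic ODE and the
// extended Balloon hemodynamic model. Fine-grid step dt must divide the
// scan interval; BOLD is sampled at scan onsets (first scan at t = 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec zdot(const mat& A, const cube& B, const mat& C,
                       const rowvec& u, const vec& z) {
  mat Aeff = A;
  for (uword j = 0; j < B.n_slices; ++j) Aeff += u[j] * B.slice(j);
  return Aeff * z + C * u.t();
}

// [[Rcpp::export(name = ".neuroRK4")]]
arma::mat neuro_rk4(const arma::mat& A, const arma::cube& B,
                    const arma::mat& C, const arma::mat& u,
                    double dt, const arma::vec& z0) {
  const uword n = u.n_rows, r = A.n_rows;
  mat Z(n, r);
  vec z = z0;
  Z.row(0) = z.t();
  for (uword k = 0; k + 1 < n; ++k) {
    rowvec u0 = u.row(k), u1 = u.row(k + 1);
    rowvec um = 0.5 * (u0 + u1);
    vec k1 = zdot(A, B, C, u0, z);
    vec k2 = zdot(A, B, C, um, z + 0.5 * dt * k1);
    vec k3 = zdot(A, B, C, um, z + 0.5 * dt * k2);
    vec k4 = zdot(A, B, C, u1, z + dt * k3);
    z += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!z.is_finite() || norm(z, "inf") > 1e6)
      Rcpp::stop("neurodynamic integration diverged (unstable parameter draw)");
    Z.row(k + 1) = z.t();
  }
  return Z;
}

// x = (s, ln f, ln v, ln q): vasodilatory signal, then log inflow, log
// venous volume and log dHb content. Log states keep f, v, q positive by
// construction (the standard robust parameterisation of the Balloon model).
static inline vec hdot(double z, const vec& x, double kappa, double gam,
                       double tau, double alpha, double E0) {
  const double s = x[0];
  const double f = std::exp(x[1]), v = std::exp(x[2]), q = std::exp(x[3]);
  const double fv = std::pow(v, 1.0 / alpha);   // outflow (Grubb)
  const double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f);
  vec d(4);
  d[0] = z - kappa * s - gam * (f - 1.0);
  d[1] = s / f;
  d[2] = (f - fv) / (tau * v);
  d[3] = (f * Ef / E0 - fv * q / v) / (tau * q);
  return d;
}

// [[Rcpp::export(name = ".balloonRK4")]]
arma::mat balloon_rk4(const arma::mat& Z, const arma::mat& h,
                      double dt, int stepsPerScan) {
  const uword n = Z.n_rows, r = Z.n_cols;
  const uword nScans = n / (uword)stepsPerScan;
  // BOLD signal equation constants (revised coefficients, 3T-era defaults)
  const double TE = 0.04, V0 = 4.0, theta0 = 40.3, r0 = 25.0;
  mat Y(nScans, r);
  for (uword j = 0; j < r; ++j) {
    const double kappa = h(j, 0), gam = h(j, 1), tau = h(j, 2),
                 alpha = h(j, 3), E0 = h(j, 4), eps = h(j, 5);
    const double k1 = 4.3 * theta0 * E0 * TE;
    const double k2 = eps * r0 * E0 * TE;
    const double k3 = 1.0 - eps;
    vec x = {0.0, 0.0, 0.0, 0.0};  // rest: s = 0, f = v = q = 1
    uword s = 0;
    for (uword k = 0; k < n; ++k) {
      if (k % (uword)stepsPerScan == 0) {
        const double v = std::exp(x[2]), q = std::exp(x[3]);
        Y(s++, j) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                          k3 * (1.0 - v));
      }
      if (k + 1 == n) break;
      const double z0 = Z(k, j), z1 = Z(k + 1, j), zm = 0.5 * (z0 + z1);
      vec k1v = hdot(z0, x, kappa, gam, tau, alpha, E0);
      vec k2v = hdot(zm, x + 0.5 * dt * k1v, kappa, gam, tau, alpha, E0);
      vec k3v = hdot(zm, x + 0.5 * dt * k2v, kappa, gam, tau, alpha, E0);
      vec k4v = hdot(z1, x + dt * k3v, kappa, gam, tau, alpha, E0);
      x += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
      if (!x.is_finite() || std::abs(x[2]) > 50.0)
        Rcpp::stop("non-physical hemodynamic state during integration");
    }
  }
  return Y;
}
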