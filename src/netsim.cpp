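// Forward integrators for the network simulator: linear neural dynamics
// with gated coupling, and the nonlinear balloon/Windkessel hemodynamic
// model. Both use fixed-step Euler on a fine grid (default 5 ms); all
// randomness (input trains, gates, noise, transit-time jitter) is drawn
// on the R side so that set.seed() governs reproducibility.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// z' = sigma * (-z + S_t z + u), where S_t[j, i] = strength * gate for
// each true edge i -> j (parent i, child j).
// u: nT x n inputs (including additive input noise);
// edges: k x 2 matrix of 1-based (parent, child);
// gate: nT x k in {0,1} (all-ones when the network is stationary).
// [[Rcpp::export]]
arma::mat neural_integrate_cpp(const arma::mat& u,
                               const arma::imat& edges,
                               const arma::vec& strength,
                               const arma::mat& gate, double sigma,
                               double dt) {
  const uword nT = u.n_rows, n = u.n_cols, k = edges.n_rows;
  mat z(nT, n, fill::zeros);
  vec state(n, fill::zeros);
  for (uword t = 0; t < nT; ++t) {
    vec acc(n, fill::zeros);
    for (uword e = 0; e < k; ++e) {
      const uword par = edges(e, 0) - 1, chi = edges(e, 1) - 1;
      acc(chi) += strength(e) * gate(t, e) * state(par);
    }
    state += dt * sigma * (-state + acc + u.row(t).t());
    if (state.has_nan() || abs(state).max() > 1e6)
      Rcpp::stop("neural integration diverged; reduce the connection "
                 "strength or the integration step");
    z.row(t) = state.t();
  }
  return z;
}

// Balloon/Windkessel transform of neural states to BOLD (percent
// signal change around 0). Per node: vasodilatory signal s, inflow f,
// venous volume v, deoxyhemoglobin q, with node-specific venous transit
// time tau0. Output on the same fine grid as the input.
// The hemodynamic states are advanced with internal substeps of at
// most 1 ms (neural input held constant within a fine step): the
// Windkessel equations become stiff for short transit times.
// [[Rcpp::export]]
arma::mat balloon_cpp(const arma::mat& z, const arma::vec& tau0,
                      double dt, double eps, double kappa, double gam,
                      double alpha, double E0, double V0) {
  const uword nT = z.n_rows, n = z.n_cols;
  const double k1 = 7.0 * E0, k2 = 2.0, k3 = 2.0 * E0 - 0.2;
  const double ialpha = 1.0 / alpha;
  const int nsub = std::max(1, (int) std::ceil(dt / 0.001));
  const double h = dt / nsub;
  mat bold(nT, n);
  vec s(n, fill::zeros), f(n, fill::ones), v(n, fill::ones),
      q(n, fill::ones);
  for (uword t = 0; t < nT; ++t) {
    for (uword j = 0; j < n; ++j) {
      for (int k = 0; k < nsub; ++k) {
        const double fout = std::pow(v(j), ialpha);
        const double Ef = 1.0 - std::pow(1.0 - E0, 1.0 / f(j));
        const double ds = eps * z(t, j) - kappa * s(j) - gam * (f(j) - 1.0);
        const double dfj = s(j);
        const double dv = (f(j) - fout) / tau0(j);
        const double dq = (f(j) * Ef / E0 - fout * q(j) / v(j)) / tau0(j);
        s(j) += h * ds;
        f(j) += h * dfj;
        v(j) += h * dv;
        q(j) += h * dq;
        if (!(f(j) > 0.0) || !(v(j) > 0.0) || !(q(j) > 0.0))
          Rcpp::stop("balloon integration produced a non-positive state "
                     "(node %d, t=%g s); reduce dt or check tau0",
                     (int) j + 1, t * dt);
      }
      bold(t, j) = 100.0 * V0 *
        (k1 * (1.0 - q(j)) + k2 * (1.0 - q(j) / v(j)) +
         k3 * (1.0 - v(j)));
    }
  }
  return bold;
}
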