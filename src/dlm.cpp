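// Discount-factor DLM filtering with unknown constant observation
// variance (normal-gamma conjugate form). The one-step forecast is
// Student-t, and the log model evidence is the sum of the forecast log
// densities accumulated in log space.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double student_t_logpdf(double e, double df, double s2) {
  // density of a t_df variable with location 0 and squared scale s2
  return R::lgammafn(0.5 * (df + 1.0)) - R::lgammafn(0.5 * df)
       - 0.5 * std::log(df * M_PI * s2)
       - 0.5 * (df + 1.0) * std::log1p(e * e / (df * s2));
}

// Core recursion. Returns log evidence; optionally fills the path
// outputs. Throws on loss of positive definiteness (negative
// eigenvalue < -1e-8 after symmetrization) or non-positive Q*.
static double run_filter(const vec& y, const mat& F, double delta,
                         const vec& m0, const mat& C0, double n0,
                         double d0, bool keep_paths, mat& m_path,
                         cube& C_path, vec& n_path, vec& d_path,
                         vec& fld) {
  const uword T = y.n_elem, p = F.n_cols;
  vec m = m0;
  mat C = C0;
  double n = n0, d = d0, logev = 0.0;

  for (uword t = 0; t < T; ++t) {
    const rowvec Ft = F.row(t);
    mat R = C / delta;                       // prior state variance at t
    double f = as_scalar(Ft * m);
    vec RF = R * Ft.t();
    double Q = as_scalar(Ft * RF) + 1.0;     // scale-free forecast var
    if (!(Q > 0.0) || !std::isfinite(Q))
      Rcpp::stop("numerical-stability error: non-positive forecast "
                 "variance at t=%d", (int) t + 1);
    double e = y(t) - f;
    double s2 = (d / n) * Q;                 // squared forecast scale
    double ld = student_t_logpdf(e, n, s2);
    logev += ld;

    vec A = RF / Q;
    m += A * e;
    C = R - (A * A.t()) * Q;
    C = 0.5 * (C + C.t());                   // symmetrize each step
    if (keep_paths) {
      vec ev = eig_sym(C);
      if (ev.min() < -1e-8)
        Rcpp::stop("numerical-stability error: posterior variance lost "
                   "positive definiteness at t=%d", (int) t + 1);
    }
    n += 1.0;
    d += e * e / Q;

    if (keep_paths) {
      m_path.row(t) = m.t();
      C_path.slice(t) = C;
      n_path(t) = n;
      d_path(t) = d;
      fld(t) = ld;
    }
  }
  return logev;
}

// [[Rcpp::export]]
Rcpp::List dlm_filter_cpp(const arma::vec& y, const arma::mat& F,
                          double delta, const arma::vec& m0,
                          const arma::mat& C0, double n0, double d0) {
  const uword T = y.n_elem, p = F.n_cols;
  mat m_path(T, p);
  cube C_path(p, p, T);
  vec n_path(T), d_path(T), fld(T);
  double logev = run_filter(y, F, delta, m0, C0, n0, d0, true, m_path,
                            C_path, n_path, d_path, fld);
  return Rcpp::List::create(
    Rcpp::Named("logEvidence") = logev,
    Rcpp::Named("mPath") = m_path,
    Rcpp::Named("CstarPath") = C_path,
    Rcpp::Named("nPath") = n_path,
    Rcpp::Named("dPath") = d_path,
    Rcpp::Named("forecastLogDens") = fld);
}

// Log evidence at each value of a discount grid (no paths kept).
// [[Rcpp::export]]
arma::vec dlm_grid_cpp(const arma::vec& y, const arma::mat& F,
                       const arma::vec& grid, const arma::vec& m0,
                       const arma::mat& C0, double n0, double d0) {
  vec out(grid.n_elem);
  mat m_dummy;
  cube C_dummy;
  vec v_dummy;
  for (uword g = 0; g < grid.n_elem; ++g)
    out(g) = run_filter(y, F, grid(g), m0, C0, n0, d0, false, m_dummy,
                        C_dummy, v_dummy, v_dummy, v_dummy);
  return out;
}
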