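// Closed-form evaluation of the linear FAO cascade dx/dt = A x + b.
// A is lower-bidiagonal (chain conversions), b a constant source vector.
// Solved exactly via the matrix exponential of the augmented system
// [[A, b], [0, 0]], which handles singular A (any k = 0) without special
// casing. Sizes are tiny (<= 9 x 9) so expmat is cheap; this path is hit
// thousands of times per optimisation run.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat cascade_matrix(const arma::vec& k) {
  const arma::uword n = k.n_elem;
  arma::mat A(n, n, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    A(i, i) = -k(i);
    if (i + 1 < n) A(i + 1, i) = k(i);
  }
  return A;
}

// [[Rcpp::export(name = ".cascade_traj_cpp")]]
NumericMatrix cascade_traj_cpp(NumericVector k, NumericVector b,
                               NumericVector x0, NumericVector times) {
  const arma::uword n = k.size();
  arma::mat M(n + 1, n + 1, arma::fill::zeros);
  M.submat(0, 0, n - 1, n - 1) = cascade_matrix(as<arma::vec>(k));
  M.submat(0, n, n - 1, n) = as<arma::vec>(b);

  arma::vec z(n + 1);
  z.head(n) = as<arma::vec>(x0);
  z(n) = 1.0;

  const int nt = times.size();
  NumericMatrix out(n, nt);

  // If all times are integer multiples of the smallest positive time the
  // grid is propagated with a single expmat and repeated matrix-vector
  // products (exact for a time-invariant system); otherwise expmat per time.
  double dt = 0.0;
  for (int j = 0; j < nt; ++j)
    if (times[j] > 0.0) { dt = times[j]; break; }
  bool uniform = dt > 0.0;
  if (uniform) {
    for (int j = 0; j < nt; ++j) {
      double r = times[j] / dt;
      if (std::fabs(r - std::round(r)) > 1e-9 * (1.0 + r)) {
        uniform = false;
        break;
      }
    }
  }
  if (uniform) {
    arma::mat E = arma::expmat(M * dt);
    arma::vec cur = z;
    long step = 0;
    for (int j = 0; j < nt; ++j) {
      long target = static_cast<long>(std::round(times[j] / dt));
      for (; step < target; ++step) cur = E * cur;
      for (arma::uword i = 0; i < n; ++i) out(i, j) = cur(i);
    }
  } else {
    for (int j = 0; j < nt; ++j) {
      arma::vec zt = times[j] == 0.0 ? z
                                     : arma::vec(arma::expmat(M * times[j]) * z);
      for (arma::uword i = 0; i < n; ++i) out(i, j) = zt(i);
    }
  }
  return out;
}

// Residual sum of squares on log10 scale for one condition's records.
// obs_species / obs_time are 0-based indices into the species order and
// the time grid; trajectory values are floored far below any measurable
// concentration so log10 stays finite if the optimiser probes extremes.
// [[Rcpp::export(name = ".cascade_rss_cpp")]]
double cascade_rss_cpp(NumericVector k, NumericVector b, NumericVector x0,
                       NumericVector times, IntegerVector obs_species,
                       IntegerVector obs_time, NumericVector obs_log10) {
  NumericMatrix traj = cascade_traj_cpp(k, b, x0, times);
  double rss = 0.0;
  const int m = obs_log10.size();
  for (int r = 0; r < m; ++r) {
    double yhat = traj(obs_species[r], obs_time[r]);
    if (yhat < 1e-300) yhat = 1e-300;
    const double res = obs_log10[r] - std::log10(yhat);
    rss += res * res;
  }
  return rss;
}
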