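#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the L1-penalized local quadratic model used by the
// proximal-Newton maxent solver:
//   min_z  g'(z - eta) + 0.5 (z - eta)' H (z - eta) + sum_j beta_j |z_j|
// Returns z.  H must be positive definite on its diagonal.
// [[Rcpp::export]]
NumericVector cd_quadratic(NumericVector eta, NumericVector g,
                           NumericMatrix H, NumericVector beta,
                           int max_sweeps = 200, double tol = 1e-12) {
  const int p = eta.size();
  NumericVector z = clone(eta);
  std::vector<double> d(p, 0.0);   // z - eta
  std::vector<double> hd(p, 0.0);  // H %*% d
  for (int sw = 0; sw < max_sweeps; ++sw) {
    double delta_max = 0.0;
    for (int j = 0; j < p; ++j) {
      const double Hjj = H(j, j);
      const double b = g[j] + hd[j] - Hjj * d[j];
      const double u = Hjj * eta[j] - b;
      const double bj = beta[j];
      double znew;
      if (u > bj)       znew = (u - bj) / Hjj;
      else if (u < -bj) znew = (u + bj) / Hjj;
      else              znew = 0.0;
      const double step = znew - z[j];
      if (step != 0.0) {
        z[j] = znew;
        d[j] = znew - eta[j];
        for (int l = 0; l < p; ++l) hd[l] += H(l, j) * step;
        const double astep = step < 0 ? -step : step;
        if (astep > delta_max) delta_max = astep;
      }
    }
    if (delta_max < tol) break;
  }
  return z;
}
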