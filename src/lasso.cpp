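#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the LASSO objective
//   (1/2n) * ||y - X beta||^2 + lambda * ||beta||_1
// X is expected column-centered (columns need not be exactly unit scale;
// per-column second moments are used in the updates). Convergence is
// declared on the KKT subgradient conditions:
//   |x_j' r / n| <= lambda + tol            when beta_j == 0
//   |x_j' r / n - lambda * sign(beta_j)| <= tol  otherwise

static inline double soft_threshold(double z, double lambda) {
  if (z > lambda) return z - lambda;
  if (z < -lambda) return z + lambda;
  return 0.0;
}

static inline const double* col_ptr(const NumericMatrix& X, int j) {
  return X.begin() + (R_xlen_t)j * X.nrow();
}

// One coordinate sweep over the index set; returns max |coef change|.
static double sweep_set(const NumericMatrix& X, std::vector<double>& r,
                        std::vector<double>& beta,
                        const std::vector<double>& xtx_n,
                        const std::vector<int>& idx, double lambda,
                        int n) {
  double max_change = 0.0;
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    int j = idx[ii];
    if (xtx_n[j] <= 0.0) continue;  // constant column: coefficient stays 0
    const double* xj = col_ptr(X, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * r[i];
    g /= n;
    double z = g + xtx_n[j] * beta[j];
    double bnew = soft_threshold(z, lambda) / xtx_n[j];
    double diff = bnew - beta[j];
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) r[i] -= diff * xj[i];
      beta[j] = bnew;
      double ad = std::fabs(diff);
      if (ad > max_change) max_change = ad;
    }
  }
  return max_change;
}

// Max KKT violation over all coordinates.
static double kkt_violation(const NumericMatrix& X,
                            const std::vector<double>& r,
                            const std::vector<double>& beta, double lambda,
                            int n, int p) {
  double worst = 0.0;
  for (int j = 0; j < p; ++j) {
    const double* xj = col_ptr(X, j);
    double g = 0.0;
    for (int i = 0; i < n; ++i) g += xj[i] * r[i];
    g /= n;
    double v;
    if (beta[j] == 0.0) {
      v = std::fabs(g) - lambda;  // negative when satisfied
      if (v < 0.0) v = 0.0;
    } else {
      v = std::fabs(g - lambda * (beta[j] > 0 ? 1.0 : -1.0));
    }
    if (v > worst) worst = v;
  }
  return worst;
}

// Convergence: KKT violation <= kkt_tol, or (when sweep_tol > 0) a full
// sweep that moves no coefficient by more than sweep_tol. The final KKT
// violation is always reported.
static List cd_fit(const NumericMatrix& X, const NumericVector& y,
                   double lambda, std::vector<double>& beta, double tol,
                   int max_iter, double sweep_tol) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> xtx_n(p);
  std::vector<int> all_idx(p);
  for (int j = 0; j < p; ++j) {
    const double* xj = col_ptr(X, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
    xtx_n[j] = s / n;
    all_idx[j] = j;
  }
  std::vector<double> r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i];
  for (int j = 0; j < p; ++j) {
    if (beta[j] != 0.0) {
      const double* xj = col_ptr(X, j);
      for (int i = 0; i < n; ++i) r[i] -= beta[j] * xj[i];
    }
  }

  const double kkt_tol = tol;
  const double inner_tol = sweep_tol > 0.0 ? sweep_tol * 0.5 : tol * 1e-2;
  bool converged = false;
  int iter = 0;
  double viol = R_PosInf;
  while (iter < max_iter) {
    // full sweep
    double ch_full = sweep_set(X, r, beta, xtx_n, all_idx, lambda, n);
    ++iter;
    if (sweep_tol > 0.0 && ch_full < sweep_tol) {
      viol = kkt_violation(X, r, beta, lambda, n, p);
      converged = true;
      break;
    }
    // iterate on the active set until stable
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (iter < max_iter) {
      double ch = sweep_set(X, r, beta, xtx_n, active, lambda, n);
      ++iter;
      if (ch < inner_tol) break;
    }
    viol = kkt_violation(X, r, beta, lambda, n, p);
    if (viol <= kkt_tol) { converged = true; break; }
  }

  NumericVector out(p);
  for (int j = 0; j < p; ++j) out[j] = beta[j];
  return List::create(_["beta"] = out, _["iterations"] = iter,
                      _["converged"] = converged,
                      _["kkt_violation"] = viol);
}

// [[Rcpp::export(name = ".cd_lasso")]]
List cd_lasso(NumericMatrix X, NumericVector y, double lambda,
              NumericVector beta_init, double tol, int max_iter,
              double sweep_tol = 0.0) {
  const int p = X.ncol();
  std::vector<double> beta(p, 0.0);
  if (beta_init.size() == (R_xlen_t)p) {
    for (int j = 0; j < p; ++j) beta[j] = beta_init[j];
  }
  return cd_fit(X, y, lambda, beta, tol, max_iter, sweep_tol);
}

// Warm-started path over a (descending) lambda grid.
// [[Rcpp::export(name = ".cd_lasso_path")]]
List cd_lasso_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                   double tol, int max_iter, double sweep_tol = 0.0) {
  const int p = X.ncol(), nl = lambdas.size();
  NumericMatrix path(p, nl);
  LogicalVector conv(nl);
  std::vector<double> beta(p, 0.0);
  for (int l = 0; l < nl; ++l) {
    List fit = cd_fit(X, y, lambdas[l], beta, tol, max_iter, sweep_tol);
    NumericVector b = fit["beta"];
    for (int j = 0; j < p; ++j) path(j, l) = b[j];
    conv[l] = fit["converged"];
  }
  return List::create(_["path"] = path, _["converged"] = conv);
}
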