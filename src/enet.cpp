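#include <Rcpp.h>
using namespace Rcpp;

// Weighted gaussian elastic-net coordinate descent over a decreasing lambda
// path with warm starts.
//
// Minimizes (1/2n) sum_i w_i (y_i - b0 - x_i'b)^2
//           + lambda * (alpha * |b|_1 + (1 - alpha)/2 * |b|_2^2)
// Columns of X and y are centered internally using the weighted mean, so the
// intercept is recovered in closed form and never penalized. Observation
// weights must sum to n (the caller normalizes).
//
// Returns list(beta = p x L matrix, intercept = length-L vector,
//              iterations = per-lambda sweep counts).
// [[Rcpp::export(name = ".enet_gaussian_path_cpp")]]
List enet_gaussian_path_cpp(NumericMatrix X, NumericVector y, NumericVector w,
                            double alpha, NumericVector lambdas,
                            double tol = 1e-9, int maxit = 100000,
                            Nullable<NumericVector> beta_init = R_NilValue) {
  const int n = X.nrow(), p = X.ncol(), L = lambdas.size();
  std::vector<double> xm(p), v(p);
  double ym = 0.0, wsum = 0.0;
  for (int i = 0; i < n; ++i) { wsum += w[i]; ym += w[i] * y[i]; }
  ym /= wsum;
  // centered copies
  NumericMatrix Xc(n, p);
  NumericVector yc(n);
  for (int j = 0; j < p; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += w[i] * X(i, j);
    m /= wsum;
    xm[j] = m;
    double vj = 0.0;
    for (int i = 0; i < n; ++i) {
      Xc(i, j) = X(i, j) - m;
      vj += w[i] * Xc(i, j) * Xc(i, j);
    }
    v[j] = vj / n;
  }
  for (int i = 0; i < n; ++i) yc[i] = y[i] - ym;

  NumericMatrix beta(p, L);
  NumericVector intercept(L);
  IntegerVector iters(L);
  std::vector<double> b(p, 0.0), r(n);
  std::vector<bool> active(p, false);
  if (beta_init.isNotNull()) {
    NumericVector b0v(beta_init);
    for (int j = 0; j < p; ++j) { b[j] = b0v[j]; if (b[j] != 0.0) active[j] = true; }
  }
  for (int i = 0; i < n; ++i) {
    double fit = 0.0;
    for (int j = 0; j < p; ++j) if (b[j] != 0.0) fit += Xc(i, j) * b[j];
    r[i] = yc[i] - fit;
  }

  for (int l = 0; l < L; ++l) {
    const double lam = lambdas[l];
    const double lam1 = lam * alpha, lam2 = lam * (1.0 - alpha);
    int it = 0;
    bool full_sweep = true;
    while (it < maxit) {
      double maxdel = 0.0;
      for (int j = 0; j < p; ++j) {
        if (!full_sweep && !active[j]) continue;
        if (v[j] <= 0.0) continue;            // zero-variance column stays 0
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += w[i] * Xc(i, j) * r[i];
        rho = rho / n + v[j] * b[j];
        double bj;
        if (rho > lam1) bj = (rho - lam1) / (v[j] + lam2);
        else if (rho < -lam1) bj = (rho + lam1) / (v[j] + lam2);
        else bj = 0.0;
        double del = bj - b[j];
        if (del != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= del * Xc(i, j);
          b[j] = bj;
          double chg = v[j] * del * del;
          if (chg > maxdel) maxdel = chg;
        }
        if (bj != 0.0) active[j] = true;
      }
      ++it;
      if (maxdel < tol) {
        if (full_sweep) break;       // converged on a verified full sweep
        full_sweep = true;           // active set converged: verify on all
      } else {
        full_sweep = false;
      }
    }
    iters[l] = it;
    double dot = 0.0;
    for (int j = 0; j < p; ++j) { beta(j, l) = b[j]; dot += b[j] * xm[j]; }
    intercept[l] = ym - dot;
  }
  return List::create(_["beta"] = beta, _["intercept"] = intercept,
                      _["iterations"] = iters);
}
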