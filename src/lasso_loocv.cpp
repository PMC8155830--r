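#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One coordinate-descent solve over a decreasing lambda path, using
// covariance updates: s[j] = sum_k XtX[j,k] beta[k] is maintained so each
// coordinate update costs O(m) independent of n. `penalty` is a 0/1
// penalty factor (0 = unpenalized, used for an intercept column of ones).
// Predictions for the held-out row are written into pred (nlambda).
static void path_solve(const std::vector<double>& XtX,
                       const std::vector<double>& Xty, int m, double n_eff,
                       const NumericVector& lambdas,
                       const std::vector<double>& penalty,
                       double tol, int max_iter,
                       const std::vector<double>& xout, double* pred) {
  std::vector<double> beta(m, 0.0), s(m, 0.0);
  std::vector<bool> active(m, false);
  for (int li = 0; li < lambdas.size(); ++li) {
    const double g = lambdas[li] / 2.0;
    int it = 0;
    while (it < max_iter) {
      // full sweep
      double delta = 0.0;
      for (int j = 0; j < m; ++j) {
        const double vj = XtX[(size_t)j * m + j] / n_eff;
        if (vj == 0.0) continue;
        double c = (Xty[j] - s[j]) / n_eff + vj * beta[j];
        double nb;
        if (penalty[j] == 0.0) nb = c / vj;
        else if (c > g) nb = (c - g) / vj;
        else if (c < -g) nb = (c + g) / vj;
        else nb = 0.0;
        if (nb != beta[j]) {
          const double d = nb - beta[j];
          const double* col = &XtX[(size_t)j * m];
          for (int k = 0; k < m; ++k) s[k] += col[k] * d;
          if (std::fabs(d) > delta) delta = std::fabs(d);
          beta[j] = nb;
        }
        active[j] = beta[j] != 0.0 || penalty[j] == 0.0;
      }
      ++it;
      if (delta < tol) break;
      // active-set sweeps
      while (it < max_iter) {
        double d2 = 0.0;
        for (int j = 0; j < m; ++j) {
          if (!active[j]) continue;
          const double vj = XtX[(size_t)j * m + j] / n_eff;
          if (vj == 0.0) continue;
          double c = (Xty[j] - s[j]) / n_eff + vj * beta[j];
          double nb;
          if (penalty[j] == 0.0) nb = c / vj;
          else if (c > g) nb = (c - g) / vj;
          else if (c < -g) nb = (c + g) / vj;
          else nb = 0.0;
          if (nb != beta[j]) {
            const double d = nb - beta[j];
            const double* col = &XtX[(size_t)j * m];
            for (int k = 0; k < m; ++k) s[k] += col[k] * d;
            if (std::fabs(d) > d2) d2 = std::fabs(d);
            beta[j] = nb;
          }
        }
        ++it;
        if (d2 < tol) break;
      }
    }
    double p = 0.0;
    for (int j = 0; j < m; ++j) p += xout[j] * beta[j];
    pred[li] = p;
  }
}

// Leave-one-out cross-validation of the LASSO over a decreasing lambda
// grid. Returns the n x nlambda matrix of squared prediction errors.
// The fold Gram matrices are rank-1 downdates of the full X'X, so each
// fold costs O(m^2 + sweeps * m^2) regardless of n.
// [[Rcpp::export(name = ".lasso_loocv_cpp")]]
NumericMatrix lasso_loocv_cpp(const NumericMatrix& x, const NumericVector& y,
                              const NumericVector& lambdas, bool intercept,
                              double tol, int max_iter) {
  const int n = x.nrow();
  const int m0 = x.ncol();
  const int m = intercept ? m0 + 1 : m0;  // optional leading ones column
  std::vector<double> X((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    if (intercept) X[(size_t)0 * n + i] = 1.0;
    for (int j = 0; j < m0; ++j)
      X[(size_t)(j + (intercept ? 1 : 0)) * n + i] = x(i, j);
  }
  std::vector<double> penalty(m, 1.0);
  if (intercept) penalty[0] = 0.0;
  // full Gram matrix and cross-products
  std::vector<double> XtX((size_t)m * m, 0.0), Xty(m, 0.0);
  for (int j = 0; j < m; ++j) {
    for (int k = j; k < m; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += X[(size_t)j * n + i] * X[(size_t)k * n + i];
      XtX[(size_t)j * m + k] = s;
      XtX[(size_t)k * m + j] = s;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X[(size_t)j * n + i] * y[i];
    Xty[j] = s;
  }
  NumericMatrix err(n, lambdas.size());
  std::vector<double> XtX_f((size_t)m * m), Xty_f(m), xi(m),
      pred(lambdas.size());
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) xi[j] = X[(size_t)j * n + i];
    for (int j = 0; j < m; ++j) {
      Xty_f[j] = Xty[j] - xi[j] * y[i];
      for (int k = 0; k < m; ++k)
        XtX_f[(size_t)j * m + k] = XtX[(size_t)j * m + k] - xi[j] * xi[k];
    }
    path_solve(XtX_f, Xty_f, m, (double)(n - 1), lambdas, penalty, tol,
               max_iter, xi, pred.data());
    for (int li = 0; li < lambdas.size(); ++li) {
      const double e = y[i] - pred[li];
      err(i, li) = e * e;
    }
  }
  return err;
}
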