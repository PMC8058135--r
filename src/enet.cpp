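#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// Coordinate descent for one lambda on centered data.
// Minimizes (1/2n)||yc - Z beta||^2 + lambda * sum_j( .5(1-alpha) b_j^2 + alpha|b_j| ).
// Z columns need not be unit variance; zsq holds (1/n) sum z_ij^2.
// r is maintained as yc - Z beta. Returns iterations used.
static int cd_fit(const NumericMatrix& Z, const std::vector<double>& zsq,
                  std::vector<double>& r, std::vector<double>& beta,
                  double lambda, double alpha, double tol, int max_iter) {
  const int n = Z.nrow(), k = Z.ncol();
  const double la = lambda * alpha, lb = lambda * (1.0 - alpha);
  int it = 0;
  for (; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < k; ++j) {
      if (zsq[j] <= 0.0) { beta[j] = 0.0; continue; }
      double rho = 0.0;
      for (int i = 0; i < n; ++i) rho += Z(i, j) * r[i];
      rho = rho / n + zsq[j] * beta[j];
      double bnew = soft(rho, la) / (zsq[j] + lb);
      double d = bnew - beta[j];
      if (d != 0.0) {
        for (int i = 0; i < n; ++i) r[i] -= Z(i, j) * d;
        beta[j] = bnew;
        double ad = std::fabs(d);
        if (ad > max_delta) max_delta = ad;
      }
    }
    if (max_delta < tol) { ++it; break; }
  }
  return it;
}

// Elastic-net path over a decreasing lambda sequence with warm starts.
// Z: n x k design (any scale; standardize upstream), y: length n.
// Columns of Z and y are centered internally; the intercept is unpenalized
// and recovered as mean(y) - colmeans(Z) . beta.
// [[Rcpp::export]]
List cpp_enet_path(NumericMatrix Z, NumericVector y, NumericVector lambda,
                   double alpha, double tol, int max_iter) {
  const int n = Z.nrow(), k = Z.ncol(), L = lambda.size();
  NumericMatrix Zc(n, k);
  std::vector<double> cmean(k), zsq(k);
  for (int j = 0; j < k; ++j) {
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += Z(i, j);
    m /= n; cmean[j] = m;
    double s = 0.0;
    for (int i = 0; i < n; ++i) { Zc(i, j) = Z(i, j) - m; s += Zc(i, j) * Zc(i, j); }
    zsq[j] = s / n;
  }
  double ym = mean(y);
  std::vector<double> r(n), beta(k, 0.0);
  for (int i = 0; i < n; ++i) r[i] = y[i] - ym;

  NumericMatrix B(k, L);
  NumericVector b0(L);
  IntegerVector iters(L);
  for (int l = 0; l < L; ++l) {
    iters[l] = cd_fit(Zc, zsq, r, beta, lambda[l], alpha, tol, max_iter);
    double dot = 0.0;
    for (int j = 0; j < k; ++j) { B(j, l) = beta[j]; dot += cmean[j] * beta[j]; }
    b0[l] = ym - dot;
  }
  return List::create(_["beta"] = B, _["intercept"] = b0, _["iterations"] = iters);
}

// Leave-one-out predictions over a lambda path.
// F: n x k raw features. For each held-out subject the remaining rows are
// standardized (mean 0, sd 1 with n_train-1 denominator; constant columns
// get sd 1), y is centered, and the warm-started path is fit; the held-out
// row is standardized with the training statistics and predicted at every
// lambda. Returns the n x L prediction matrix.
// [[Rcpp::export]]
NumericMatrix cpp_enet_loo(NumericMatrix F, NumericVector y, NumericVector lambda,
                           double alpha, double tol, int max_iter) {
  const int n = F.nrow(), k = F.ncol(), L = lambda.size();
  const int m = n - 1;
  NumericMatrix pred(n, L);
  NumericMatrix Z(m, k);
  std::vector<double> mu(k), sd(k), zsq(k), r(m), beta(k), znew(k);

  for (int hold = 0; hold < n; ++hold) {
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) if (i != hold) s += F(i, j);
      mu[j] = s / m;
      double v = 0.0;
      for (int i = 0; i < n; ++i) if (i != hold) {
        double d = F(i, j) - mu[j]; v += d * d;
      }
      sd[j] = (m > 1) ? std::sqrt(v / (m - 1)) : 1.0;
      if (sd[j] <= 0.0) sd[j] = 1.0;
      int row = 0;
      for (int i = 0; i < n; ++i) if (i != hold) {
        Z(row++, j) = (F(i, j) - mu[j]) / sd[j];
      }
      zsq[j] = v / (sd[j] * sd[j]) / m;  // (1/m) sum Z^2, Z has exact mean 0
      znew[j] = (F(hold, j) - mu[j]) / sd[j];
    }
    double ym = 0.0;
    for (int i = 0; i < n; ++i) if (i != hold) ym += y[i];
    ym /= m;
    int row = 0;
    for (int i = 0; i < n; ++i) if (i != hold) r[row++] = y[i] - ym;
    std::fill(beta.begin(), beta.end(), 0.0);

    for (int l = 0; l < L; ++l) {
      cd_fit(Z, zsq, r, beta, lambda[l], alpha, tol, max_iter);
      double yhat = ym;
      for (int j = 0; j < k; ++j) yhat += znew[j] * beta[j];
      pred(hold, l) = yhat;
    }
  }
  return pred;
}

// Gram-form lasso: minimize .5 f'Gf - c'f + lambda ||f||_1, warm start f0.
// Used for the sparse-coding step of dictionary learning (G = W'W, c = W'x).
// [[Rcpp::export]]
NumericVector cpp_lasso_gram(NumericMatrix G, NumericVector c, double lambda,
                             NumericVector f0, double tol, int max_iter) {
  const int k = c.size();
  NumericVector f = clone(f0);
  for (int it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < k; ++j) {
      if (G(j, j) <= 0.0) { f[j] = 0.0; continue; }
      double g = c[j];
      for (int l = 0; l < k; ++l) if (l != j) g -= G(j, l) * f[l];
      double fnew = soft(g, lambda) / G(j, j);
      double ad = std::fabs(fnew - f[j]);
      f[j] = fnew;
      if (ad > max_delta) max_delta = ad;
    }
    if (max_delta < tol) break;
  }
  return f;
}

// Gram-form nonnegative least squares by coordinate descent:
// minimize .5 f'Gf - c'f subject to f >= 0. Used for the NNMF transform.
// [[Rcpp::export]]
NumericVector cpp_nnls_gram(NumericMatrix G, NumericVector c,
                            NumericVector f0, double tol, int max_iter) {
  const int k = c.size();
  NumericVector f = clone(f0);
  for (int it = 0; it < max_iter; ++it) {
    double max_delta = 0.0;
    for (int j = 0; j < k; ++j) {
      if (G(j, j) <= 0.0) { f[j] = 0.0; continue; }
      double g = c[j];
      for (int l = 0; l < k; ++l) if (l != j) g -= G(j, l) * f[l];
      double fnew = g / G(j, j);
      if (fnew < 0.0) fnew = 0.0;
      double ad = std::fabs(fnew - f[j]);
      f[j] = fnew;
      if (ad > max_delta) max_delta = ad;
    }
    if (max_delta < tol) break;
  }
  return f;
}
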