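// Epsilon-insensitive support-vector regression via sequential minimal
// optimization on the standard 2n-variable dual (alpha / alpha-star blocks),
// with first-order maximal-violating-pair working-set selection and a dense
// precomputed kernel matrix. Problem sizes here are small (n <= ~1,500), so
// no shrinking or cache eviction is needed.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static double kernel_eval(const double* xi, const double* xj, int p,
                          int kernel, double gamma, int degree, double coef0) {
  double dot = 0.0, dist2 = 0.0;
  for (int k = 0; k < p; ++k) {
    double d = xi[k] - xj[k];
    dot += xi[k] * xj[k];
    dist2 += d * d;
  }
  switch (kernel) {
  case 0: return dot;                                   // linear
  case 1: return std::pow(gamma * dot + coef0, degree); // polynomial
  default: return std::exp(-gamma * dist2);             // radial
  }
}

// [[Rcpp::export]]
List svr_smo_cpp(NumericMatrix X, NumericVector y, double C, double eps,
                 int kernel, double gamma, int degree, double coef0,
                 double tol, int max_iter) {
  const int n = X.nrow(), p = X.ncol();
  // row-major copies of the samples for cheap pointer access
  std::vector<double> xs((size_t)n * p);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) xs[(size_t)i * p + k] = X(i, k);

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = kernel_eval(&xs[(size_t)i * p], &xs[(size_t)j * p], p,
                             kernel, gamma, degree, coef0);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  // variables t in [0, 2n): t < n -> alpha_i (sign +1), else alpha*_i (-1)
  const int m2 = 2 * n;
  std::vector<double> a(m2, 0.0), G(m2);
  for (int i = 0; i < n; ++i) {
    G[i] = eps - y[i];
    G[n + i] = eps + y[i];
  }
  auto sgn = [n](int t) { return t < n ? 1.0 : -1.0; };
  auto row = [n](int t) { return t < n ? t : t - n; };

  int iter = 0;
  bool converged = false;
  double m_up = 0.0, m_low = 0.0;
  const double tau = 1e-12;

  while (iter < max_iter) {
    // libsvm-style second-order working-set selection: i maximizes the
    // violation -s_t G_t over I_up; j maximizes the guaranteed decrease
    // b^2 / a among I_low members that violate against i
    int ti = -1, tj = -1;
    m_up = -HUGE_VAL; m_low = HUGE_VAL;
    for (int t = 0; t < m2; ++t) {
      double s = sgn(t), v = -s * G[t];
      bool in_up = (s > 0) ? (a[t] < C) : (a[t] > 0);
      if (in_up && v > m_up) { m_up = v; ti = t; }
    }
    if (ti < 0) { converged = true; break; }
    const int ri0 = row(ti);
    const double* Ki0 = &K[(size_t)ri0 * n];
    const double kii = Ki0[ri0];
    double best_gain = -HUGE_VAL;
    for (int t = 0; t < m2; ++t) {
      double s = sgn(t), v = -s * G[t];
      bool in_low = (s > 0) ? (a[t] > 0) : (a[t] < C);
      if (!in_low) continue;
      if (v < m_low) m_low = v;
      double b = m_up - v;
      if (b <= 0) continue;
      double quad = kii + K[(size_t)row(t) * n + row(t)] - 2.0 * Ki0[row(t)];
      if (quad <= tau) quad = tau;
      double gain = b * b / quad;
      if (gain > best_gain) { best_gain = gain; tj = t; }
    }
    if (tj < 0 || m_up - m_low < tol) { converged = true; break; }

    int ri = row(ti), rj = row(tj);
    double si = sgn(ti), sj = sgn(tj);
    double quad = K[(size_t)ri * n + ri] + K[(size_t)rj * n + rj] -
                  2.0 * K[(size_t)ri * n + rj];
    if (quad <= tau) quad = tau;
    double b_ij = m_up - (-sgn(tj) * G[tj]);
    double d = b_ij / quad;  // unconstrained optimum, > 0
    // box constraints: a_ti + si*d in [0,C], a_tj - sj*d in [0,C]
    double dmax = (si > 0) ? (C - a[ti]) : a[ti];
    double dmax2 = (sj > 0) ? a[tj] : (C - a[tj]);
    if (dmax2 < dmax) dmax = dmax2;
    if (d > dmax) d = dmax;
    if (d <= 0) { converged = true; break; }

    a[ti] += si * d;
    a[tj] -= sj * d;
    const double* Ki = &K[(size_t)ri * n];
    const double* Kj = &K[(size_t)rj * n];
    for (int t = 0; t < m2; ++t) {
      double s = sgn(t);
      G[t] += s * d * (Ki[row(t)] - Kj[row(t)]);
    }
    ++iter;
  }

  // intercept: b equals -s_t G_t at free variables; fallback to midpoint
  double bsum = 0.0; int bcnt = 0;
  for (int t = 0; t < m2; ++t) {
    if (a[t] > tau && a[t] < C - tau) { bsum += -sgn(t) * G[t]; ++bcnt; }
  }
  double b = bcnt > 0 ? bsum / bcnt : 0.5 * (m_up + m_low);

  NumericVector beta(n);
  for (int i = 0; i < n; ++i) beta[i] = a[i] - a[n + i];
  return List::create(_["beta"] = beta, _["b"] = b,
                      _["iterations"] = iter, _["converged"] = converged);
}

// [[Rcpp::export]]
NumericVector svr_predict_cpp(NumericMatrix SV, NumericVector beta, double b,
                              NumericMatrix X, int kernel, double gamma,
                              int degree, double coef0) {
  const int nsv = SV.nrow(), p = SV.ncol(), n = X.nrow();
  std::vector<double> sv((size_t)nsv * p), xx((size_t)n * p);
  for (int i = 0; i < nsv; ++i)
    for (int k = 0; k < p; ++k) sv[(size_t)i * p + k] = SV(i, k);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < p; ++k) xx[(size_t)i * p + k] = X(i, k);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double f = b;
    for (int j = 0; j < nsv; ++j)
      f += beta[j] * kernel_eval(&xx[(size_t)i * p], &sv[(size_t)j * p], p,
                                 kernel, gamma, degree, coef0);
    out[i] = f;
  }
  return out;
}
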