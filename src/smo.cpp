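#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimisation for the soft-margin C-SVC dual with an RBF
// kernel, maximal-violating-pair working-set selection and the standard
// KKT-gap stopping rule. Problem sizes here (n <= ~1500, d = 10) allow the
// full kernel matrix to be precomputed.

static inline double rbf_kernel(const double* a, const double* b, int d,
                                double gamma) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    const double t = a[k] - b[k];
    s += t * t;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_train(NumericMatrix X, IntegerVector y, double C, double gamma,
               double eps = 1e-3, int max_iter = 1000000) {
  const int n = X.nrow(), d = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  for (int t = 0; t < n; ++t)
    if (y[t] != 1 && y[t] != -1) stop("labels must be +1/-1");

  // row-contiguous copy (Rcpp matrices are column-major)
  std::vector<double> Xr((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < d; ++k) Xr[(size_t)i * d + k] = X(i, k);

  std::vector<double> K((size_t)n * n);
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double v = rbf_kernel(&Xr[(size_t)i * d], &Xr[(size_t)j * d], d, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);  // G = grad(1/2 a'Qa - e'a)
  const double tau = 1e-12;
  int iter = 0;
  double gap = R_PosInf;
  for (; iter < max_iter; ++iter) {
    // first-order choice of i, second-order choice of j (LIBSVM WSS2)
    int i = -1, j = -1;
    double gmax = -R_PosInf, gmin = R_PosInf;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      if (up && v > gmax) { gmax = v; i = t; }
    }
    if (i >= 0) {
      const double* Ki_row = &K[(size_t)i * n];
      double best = R_PosInf;
      for (int t = 0; t < n; ++t) {
        const double v = -y[t] * G[t];
        const bool low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
        if (!low) continue;
        if (v < gmin) gmin = v;
        const double b = gmax - v;
        if (b > 0) {
          double a = 2.0 - 2.0 * Ki_row[t];  // K_ii + K_tt - 2K_it, RBF diag = 1
          if (a <= 0) a = tau;
          const double score = -(b * b) / a;
          if (score < best) { best = score; j = t; }
        }
      }
    }
    gap = gmax - gmin;
    if (i < 0 || j < 0 || gap < eps) break;

    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = tau;
    const double old_ai = alpha[i], old_aj = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0) {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; }
      }
      if (diff > 0) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; }
      } else {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > C) {
        if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; }
      } else {
        if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; }
      }
      if (sum > C) {
        if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; }
      } else {
        if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;  // numerical stall
    const double* Ki = &K[(size_t)i * n];
    const double* Kj = &K[(size_t)j * n];
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * Ki[t] * dai + y[j] * Kj[t] * daj);
  }

  // offset: average y*G over free SVs, else midpoint of the KKT interval
  double rho;
  int nfree = 0;
  double sum_yG = 0.0, m_up = -R_PosInf, m_low = R_PosInf;
  for (int t = 0; t < n; ++t) {
    const double yG = y[t] * G[t];
    const double v = -yG;
    const bool up  = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
    const bool low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
    if (alpha[t] > 0 && alpha[t] < C) { ++nfree; sum_yG += yG; }
    if (up && v > m_up) m_up = v;
    if (low && v < m_low) m_low = v;
  }
  rho = nfree > 0 ? sum_yG / nfree : -(m_up + m_low) / 2.0;

  std::vector<int> sv;
  sv.reserve(n);
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 0) sv.push_back(t);
  const int nsv = (int)sv.size();
  NumericMatrix SV(nsv, d);
  NumericVector coef(nsv);
  IntegerVector sv_index(nsv);
  for (int s = 0; s < nsv; ++s) {
    const int t = sv[s];
    for (int k = 0; k < d; ++k) SV(s, k) = X(t, k);
    coef[s] = alpha[t] * y[t];
    sv_index[s] = t + 1;  // 1-based for R
  }

  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["sv_index"] = sv_index, _["iterations"] = iter,
                      _["kkt_gap"] = gap, _["converged"] = (gap < eps));
}

// Decision values f(x) = sum_s coef_s K(sv_s, x) - rho for each row of Xnew.
// [[Rcpp::export]]
NumericVector rbf_decision(NumericMatrix SV, NumericVector coef, double rho,
                           double gamma, NumericMatrix Xnew) {
  const int nsv = SV.nrow(), d = SV.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != d) stop("feature arity mismatch");
  std::vector<double> Sr((size_t)nsv * d), Zr((size_t)m * d);
  for (int i = 0; i < nsv; ++i)
    for (int k = 0; k < d; ++k) Sr[(size_t)i * d + k] = SV(i, k);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) Zr[(size_t)i * d + k] = Xnew(i, k);
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double f = -rho;
    for (int s = 0; s < nsv; ++s)
      f += coef[s] * rbf_kernel(&Sr[(size_t)s * d], &Zr[(size_t)i * d], d, gamma);
    out[i] = f;
  }
  return out;
}
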