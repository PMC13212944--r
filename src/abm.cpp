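// Fractional Adams-Bashforth-Moulton predictor-corrector (PECE) cores.
//
// Each state component i with Caputo order alpha_i is advanced by the
// standard fractional Adams scheme built from the Riemann-Liouville kernel
// (t - tau)^(alpha-1)/Gamma(alpha):
//
//   predictor: x_{n+1}^P = x_0 + h^a/Gamma(a+1) * sum_{j=0}^{n} b_{n-j} f_j,
//              b_m = (m+1)^a - m^a
//   corrector: x_{n+1}   = x_0 + h^a/Gamma(a+2) *
//              [ f(t_{n+1}, x^P) + c0(n) f_0 + sum_{j=1}^{n} d_{n+1-j} f_j ],
//              c0(n) = n^(a+1) - (n-a)(n+1)^a,
//              d_m   = (m+1)^(a+1) + (m-1)^(a+1) - 2 m^(a+1)
//
// Full-memory sums (no truncation), so cost is O(N^2); this inner loop is the
// reason the solver lives in C++.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Weights {
  std::vector<double> b;   // b[m], m = 0..N
  std::vector<double> d;   // d[m], m = 1..N+1 (index m)
  double ga1, ga2;         // Gamma(a+1), Gamma(a+2)
  double ha1, ha2;         // h^a/Gamma(a+1), h^a/Gamma(a+2)
  double alpha;
};

Weights make_weights(double alpha, double h, int N) {
  Weights w;
  w.alpha = alpha;
  w.ga1 = std::tgamma(alpha + 1.0);
  w.ga2 = std::tgamma(alpha + 2.0);
  w.ha1 = std::pow(h, alpha) / w.ga1;
  w.ha2 = std::pow(h, alpha) / w.ga2;
  w.b.resize(N + 1);
  for (int m = 0; m <= N; ++m)
    w.b[m] = std::pow(m + 1.0, alpha) - std::pow((double)m, alpha);
  w.d.resize(N + 2);
  for (int m = 1; m <= N + 1; ++m)
    w.d[m] = std::pow(m + 1.0, alpha + 1.0) + std::pow(m - 1.0, alpha + 1.0)
           - 2.0 * std::pow((double)m, alpha + 1.0);
  return w;
}

inline double c0_weight(double alpha, int n) {
  return std::pow((double)n, alpha + 1.0) - (n - alpha) * std::pow(n + 1.0, alpha);
}

inline bool bad(double v, double guard) {
  return !std::isfinite(v) || std::fabs(v) > guard;
}

}  // namespace

// Generic system with an R callback f(t, x) -> numeric vector.
// [[Rcpp::export]]
List abm_pece_cpp(Function f, NumericVector alphas, NumericVector x0,
                  double h, int N, int n_corr, double guard) {
  const int d = x0.size();
  NumericMatrix X(N + 1, d);
  NumericMatrix F(N + 1, d);
  std::vector<Weights> W;
  W.reserve(d);
  for (int i = 0; i < d; ++i) W.push_back(make_weights(alphas[i], h, N));

  for (int i = 0; i < d; ++i) X(0, i) = x0[i];
  NumericVector f0 = f(0.0, x0);
  for (int i = 0; i < d; ++i) F(0, i) = f0[i];

  int diverged_at = -1;
  int n_done = 0;
  NumericVector xp(d), xc(d);
  for (int n = 0; n < N; ++n) {
    double tn1 = (n + 1) * h;
    for (int i = 0; i < d; ++i) {
      double s = 0.0;
      const std::vector<double>& b = W[i].b;
      for (int j = 0; j <= n; ++j) s += b[n - j] * F(j, i);
      xp[i] = x0[i] + W[i].ha1 * s;
    }
    NumericVector fp = f(tn1, xp);
    for (int it = 0; it < n_corr; ++it) {
      for (int i = 0; i < d; ++i) {
        double s = c0_weight(W[i].alpha, n) * F(0, i);
        const std::vector<double>& dv = W[i].d;
        for (int j = 1; j <= n; ++j) s += dv[n + 1 - j] * F(j, i);
        xc[i] = x0[i] + W[i].ha2 * (fp[i] + s);
      }
      if (it + 1 < n_corr) fp = f(tn1, xc);
    }
    bool div = false;
    for (int i = 0; i < d; ++i) if (bad(xc[i], guard)) div = true;
    if (div) { diverged_at = n + 1; break; }
    NumericVector fc = f(tn1, xc);
    for (int i = 0; i < d; ++i) { X(n + 1, i) = xc[i]; F(n + 1, i) = fc[i]; }
    n_done = n + 1;
  }
  return List::create(_["states"] = X, _["n_done"] = n_done,
                      _["diverged_at"] = diverged_at);
}

// Chain-reduced distributed-delay models, hardcoded right-hand sides.
// variant 1: dx = rho*x - rho*y^2, dy = x - a*y
// variant 2: dx = rho*x - rho*y,   dy = x^2 - a*y
// [[Rcpp::export]]
List abm_chain_cpp(int variant, double alpha1, double rho, double a,
                   double x0, double y0, double h, int N, int n_corr,
                   double guard) {
  NumericMatrix X(N + 1, 2), F(N + 1, 2);
  Weights Wx = make_weights(alpha1, h, N);
  Weights Wy = make_weights(1.0, h, N);
  X(0, 0) = x0; X(0, 1) = y0;
  auto fx = [&](double x, double y) {
    return variant == 1 ? rho * x - rho * y * y : rho * x - rho * y;
  };
  auto fy = [&](double x, double y) {
    return variant == 1 ? x - a * y : x * x - a * y;
  };
  F(0, 0) = fx(x0, y0); F(0, 1) = fy(x0, y0);

  int diverged_at = -1, n_done = 0;
  for (int n = 0; n < N; ++n) {
    double sx = 0.0, sy = 0.0;
    for (int j = 0; j <= n; ++j) {
      sx += Wx.b[n - j] * F(j, 0);
      sy += Wy.b[n - j] * F(j, 1);
    }
    double xp = x0 + Wx.ha1 * sx;
    double yp = y0 + Wy.ha1 * sy;
    double fpx = fx(xp, yp), fpy = fy(xp, yp);
    double xc = xp, yc = yp;
    for (int it = 0; it < n_corr; ++it) {
      double cx = c0_weight(alpha1, n) * F(0, 0);
      double cy = c0_weight(1.0, n) * F(0, 1);
      for (int j = 1; j <= n; ++j) {
        cx += Wx.d[n + 1 - j] * F(j, 0);
        cy += Wy.d[n + 1 - j] * F(j, 1);
      }
      xc = x0 + Wx.ha2 * (fpx + cx);
      yc = y0 + Wy.ha2 * (fpy + cy);
      if (it + 1 < n_corr) { fpx = fx(xc, yc); fpy = fy(xc, yc); }
    }
    if (bad(xc, guard) || bad(yc, guard)) { diverged_at = n + 1; break; }
    X(n + 1, 0) = xc; X(n + 1, 1) = yc;
    F(n + 1, 0) = fx(xc, yc); F(n + 1, 1) = fy(xc, yc);
    n_done = n + 1;
  }
  return List::create(_["states"] = X, _["n_done"] = n_done,
                      _["diverged_at"] = diverged_at);
}

// Delayed logistic equation dx = rho*x(t) - rho*x(t - r)^2 with the delayed
// state read from the solution grid (index shift L = r/h) and from the
// pre-evaluated history phi on t <= 0. phi[j] = phi((j - L) h), j = 0..L.
// [[Rcpp::export]]
List abm_logistic_dde_cpp(double alpha, double rho, int L, NumericVector phi,
                          double h, int N, int n_corr, double guard) {
  NumericVector y(N + 1), F(N + 1);
  double y0 = phi[L];
  y[0] = y0;
  Weights W = make_weights(alpha, h, N);
  auto delayed = [&](int k, double yk) -> double {
    // state at t_k - r = (k - L) h; yk is the value at index k (used when L=0)
    if (L == 0) return yk;
    int m = k - L;
    if (m <= 0) return phi[m + L];
    return y[m];
  };
  auto rhs = [&](int k, double yk) {
    double yd = delayed(k, yk);
    return rho * yk - rho * yd * yd;
  };
  F[0] = rhs(0, y0);
  int diverged_at = -1, n_done = 0;
  for (int n = 0; n < N; ++n) {
    double s = 0.0;
    for (int j = 0; j <= n; ++j) s += W.b[n - j] * F[j];
    double yp = y0 + W.ha1 * s;
    double fp = rhs(n + 1, yp);
    double yc = yp;
    for (int it = 0; it < n_corr; ++it) {
      double c = c0_weight(alpha, n) * F[0];
      for (int j = 1; j <= n; ++j) c += W.d[n + 1 - j] * F[j];
      yc = y0 + W.ha2 * (fp + c);
      if (it + 1 < n_corr) fp = rhs(n + 1, yc);
    }
    if (bad(yc, guard)) { diverged_at = n + 1; break; }
    y[n + 1] = yc;
    F[n + 1] = rhs(n + 1, yc);
    n_done = n + 1;
  }
  return List::create(_["states"] = y, _["n_done"] = n_done,
                      _["diverged_at"] = diverged_at);
}
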