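#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// check (pinball) loss of the line y = b0 + b1 * x at quantile tau:
// rho_tau(r) = tau * r + max(-r, 0)
static double pinball(const double* x, const double* y, int n, double b0,
                      double b1, double tau) {
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - b0 - b1 * x[i];
    s += tau * r + std::max(-r, 0.0);
  }
  return s;
}

// [[Rcpp::export]]
double pinball_loss_cpp(NumericVector x, NumericVector y, double b0,
                        double b1, double tau) {
  return pinball(x.begin(), y.begin(), x.size(), b0, b1, tau);
}

// lower tau-quantile (type 1) of z: a minimizer of sum rho_tau(z - b)
static double tau_quantile(std::vector<double>& z, double tau) {
  const int n = (int)z.size();
  int k = (int)std::ceil(tau * n);
  if (k < 1) k = 1;
  if (k > n) k = n;
  std::nth_element(z.begin(), z.begin() + (k - 1), z.end());
  return z[k - 1];
}

// g(s) = min_b0 sum rho_tau(y - s x - b0); work is a reusable buffer
static double g_of_slope(const double* x, const double* y, int n, double s,
                         double tau, std::vector<double>& work,
                         double* b0_out) {
  work.resize(n);
  for (int i = 0; i < n; ++i) work[i] = y[i] - s * x[i];
  double b0 = tau_quantile(work, tau);
  if (b0_out) *b0_out = b0;
  return pinball(x, y, n, b0, s, tau);
}

// lexicographic tie-break on (b0, b1) among losses equal within rel. tol
static bool better(double loss, double b0, double b1, double best_loss,
                   double best_b0, double best_b1, double scale) {
  double tol = 1e-10 * (1.0 + scale);
  if (loss < best_loss - tol) return true;
  if (loss > best_loss + tol) return false;
  if (b0 < best_b0 - 1e-12) return true;
  if (b0 > best_b0 + 1e-12) return false;
  return b1 < best_b1 - 1e-12;
}

// Fit y = b0 + b1 x minimizing the check loss.
// n <= n_exact: exact enumeration of all lines through point pairs with
// distinct x (an optimum of this 2-parameter LP interpolates two points),
// ties broken toward the lexicographically smallest (b0, b1).
// n > n_exact: golden-section search on the convex piecewise-linear slope
// profile g(s), followed by a snap step that replaces the numeric optimum
// with the best interpolating line through near-active points when that
// does not increase the loss.
// [[Rcpp::export]]
NumericVector qr_fit_line_cpp(NumericVector xv, NumericVector yv, double tau,
                              int n_exact) {
  const int n = xv.size();
  const double* x = xv.begin();
  const double* y = yv.begin();
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  if (xmax - xmin <= 0)
    stop("slope unidentifiable: all abscissae identical");
  double yscale = ymax - ymin;

  if (n <= n_exact) {
    double best_loss = R_PosInf, best_b0 = R_PosInf, best_b1 = R_PosInf;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[j] - x[i];
        if (dx == 0) continue;
        double b1 = (y[j] - y[i]) / dx;
        double b0 = y[i] - b1 * x[i];
        double loss = pinball(x, y, n, b0, b1, tau);
        if (better(loss, b0, b1, best_loss, best_b0, best_b1, yscale)) {
          best_loss = loss; best_b0 = b0; best_b1 = b1;
        }
      }
    }
    return NumericVector::create(best_b0, best_b1, best_loss);
  }

  // slope bracket: an optimal line passes through two data points
  std::vector<double> ux(x, x + n);
  std::sort(ux.begin(), ux.end());
  double dxmin = R_PosInf;
  for (int i = 1; i < n; ++i) {
    double d = ux[i] - ux[i - 1];
    if (d > 1e-12 && d < dxmin) dxmin = d;
  }
  double smax = (yscale > 0 ? yscale : 1.0) / dxmin + 1.0;
  double lo = -smax, hi = smax;
  std::vector<double> work;
  const double invphi = (std::sqrt(5.0) - 1.0) / 2.0;
  double m1 = hi - invphi * (hi - lo), m2 = lo + invphi * (hi - lo);
  double g1 = g_of_slope(x, y, n, m1, tau, work, nullptr);
  double g2 = g_of_slope(x, y, n, m2, tau, work, nullptr);
  for (int it = 0; it < 200 && (hi - lo) > 1e-9 * (1.0 + smax); ++it) {
    if (g1 <= g2) {
      hi = m2; m2 = m1; g2 = g1;
      m1 = hi - invphi * (hi - lo);
      g1 = g_of_slope(x, y, n, m1, tau, work, nullptr);
    } else {
      lo = m1; m1 = m2; g1 = g2;
      m2 = lo + invphi * (hi - lo);
      g2 = g_of_slope(x, y, n, m2, tau, work, nullptr);
    }
  }
  double b0;
  double s = (lo + hi) / 2.0;
  double loss = g_of_slope(x, y, n, s, tau, work, &b0);

  // snap: try lines through the points closest to the numeric optimum
  std::vector<std::pair<double, int> > near;
  near.reserve(n);
  for (int i = 0; i < n; ++i)
    near.push_back(std::make_pair(std::fabs(y[i] - b0 - s * x[i]), i));
  int m = std::min(n, 12);
  std::partial_sort(near.begin(), near.begin() + m, near.end());
  double best_loss = loss, best_b0 = b0, best_b1 = s;
  bool snapped = false;
  for (int a = 0; a < m - 1; ++a) {
    for (int b = a + 1; b < m; ++b) {
      int i = near[a].second, j = near[b].second;
      double dx = x[j] - x[i];
      if (std::fabs(dx) < 1e-12) continue;
      double b1c = (y[j] - y[i]) / dx;
      double b0c = y[i] - b1c * x[i];
      double lc = pinball(x, y, n, b0c, b1c, tau);
      if (lc <= best_loss + 1e-10 * (1.0 + yscale) &&
          better(lc, b0c, b1c, snapped ? best_loss : R_PosInf,
                 snapped ? best_b0 : R_PosInf,
                 snapped ? best_b1 : R_PosInf, yscale)) {
        best_loss = lc; best_b0 = b0c; best_b1 = b1c; snapped = true;
      }
    }
  }
  return NumericVector::create(best_b0, best_b1, best_loss);
}
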