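#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVM dual with linear kernel:
//   max  sum(alpha) - 1/2 alpha' Q alpha,  Q_ij = y_i y_j K_ij
//   s.t. 0 <= alpha_i <= C,  sum_i alpha_i y_i = 0
// Working-set selection is the maximal violating pair; the equality
// constraint carries the unregularized bias.  K is the precomputed Gram
// matrix of the (already normalized) training rows, so repeated fits on
// row subsets of one cohort can share a single tcrossprod().
//
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double cost, double eps,
               int max_iter) {
  const int n = K.nrow();
  if (K.ncol() != n) stop("K must be square");
  if (y.size() != n) stop("length(y) must match nrow(K)");
  const double TAU = 1e-12;

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of 1/2 a'Qa - sum(a)

  int iter = 0;
  double Gmax = 0.0, Gmin = 0.0;
  while (iter < max_iter) {
    int i = -1, j = -1;
    Gmax = -INFINITY;
    Gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      const double v = -y[t] * G[t];
      const bool in_up = (y[t] == 1 && alpha[t] < cost) ||
                         (y[t] == -1 && alpha[t] > 0.0);
      const bool in_low = (y[t] == 1 && alpha[t] > 0.0) ||
                          (y[t] == -1 && alpha[t] < cost);
      if (in_up && v > Gmax) { Gmax = v; i = t; }
      if (in_low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0.0) quad = TAU;
    const double ai_old = alpha[i], aj_old = alpha[j];

    if (y[i] != y[j]) {
      const double delta = (-G[i] - G[j]) / quad;
      const double diff = alpha[i] - alpha[j];
      alpha[i] += delta;
      alpha[j] += delta;
      if (diff > 0.0) {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = diff; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = -diff; }
      }
      if (diff > 0.0) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = cost - diff; }
      } else {
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = cost + diff; }
      }
    } else {
      const double delta = (G[i] - G[j]) / quad;
      const double sum = alpha[i] + alpha[j];
      alpha[i] -= delta;
      alpha[j] += delta;
      if (sum > cost) {
        if (alpha[i] > cost) { alpha[i] = cost; alpha[j] = sum - cost; }
      } else {
        if (alpha[j] < 0.0) { alpha[j] = 0.0; alpha[i] = sum; }
      }
      if (sum > cost) {
        if (alpha[j] > cost) { alpha[j] = cost; alpha[i] = sum - cost; }
      } else {
        if (alpha[i] < 0.0) { alpha[i] = 0.0; alpha[j] = sum; }
      }
    }

    const double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
    ++iter;
  }

  // bias from KKT: free SVs give b = -y_t G_t exactly; otherwise midpoint
  // of the feasible interval [Gmin, Gmax] of -yG.
  double b = 0.0;
  int n_free = 0;
  const double bound_tol = 1e-10 * (cost > 1.0 ? cost : 1.0);
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > bound_tol && alpha[t] < cost - bound_tol) {
      b += -y[t] * G[t];
      ++n_free;
    }
  }
  if (n_free > 0) {
    b /= n_free;
  } else {
    b = (Gmax + Gmin) / 2.0;
  }

  double dual_obj = 0.0;  // sum(a) - 1/2 a'Qa
  for (int t = 0; t < n; ++t) dual_obj += alpha[t] - 0.5 * alpha[t] * (G[t] + 1.0);

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["dual_objective"] = dual_obj,
                      _["iterations"] = iter, _["kkt_gap"] = Gmax - Gmin);
}
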