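// Block coordinate descent for the graphical lasso (off-diagonal penalty
// only): the hot loops behind glasso_core(). W is the working covariance
// estimate (diagonal fixed at diag(S)); B stores the lasso coefficients
// of each column's subproblem for warm starts along a penalty path.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_core_cpp(NumericMatrix S_, double lambda, double tol,
                     int max_sweeps, NumericMatrix B_) {
  const int p = S_.ncol();
  NumericMatrix W = clone(S_);
  NumericMatrix B = clone(B_);
  const int q = p - 1;

  double mean_off = 0.0;
  for (int j = 1; j < p; ++j)
    for (int i = 0; i < j; ++i) mean_off += std::fabs(S_(i, j));
  mean_off /= (p * q) / 2.0;
  const double thr = tol * mean_off;
  const double inner_tol = std::min(thr / 10.0, 1e-7);

  std::vector<int> idx(q);
  bool converged = false;
  int sweeps = 0;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    sweeps = sweep + 1;
    double change = 0.0;
    for (int j = 0; j < p; ++j) {
      int k = 0;
      for (int i = 0; i < p; ++i)
        if (i != j) idx[k++] = i;
      // lasso: 0.5 b' A b - s' b + lambda |b|_1, A = W[idx, idx]
      for (int it = 0; it < 2000; ++it) {
        double dmax = 0.0;
        for (int a = 0; a < q; ++a) {
          const int ia = idx[a];
          double r = S_(ia, j);
          for (int b = 0; b < q; ++b)
            if (b != a) r -= W(ia, idx[b]) * B(b, j);
          const double bj = soft(r, lambda) / W(ia, ia);
          const double d = std::fabs(bj - B(a, j));
          if (d > dmax) dmax = d;
          B(a, j) = bj;
        }
        if (dmax < inner_tol) break;
      }
      for (int a = 0; a < q; ++a) {
        const int ia = idx[a];
        double w12 = 0.0;
        for (int b = 0; b < q; ++b) w12 += W(ia, idx[b]) * B(b, j);
        change += std::fabs(W(ia, j) - w12);
        W(ia, j) = w12;
        W(j, ia) = w12;
      }
    }
    if (change / (p * q) < thr) {
      converged = true;
      break;
    }
  }

  NumericMatrix theta(p, p);
  for (int j = 0; j < p; ++j) {
    int k = 0;
    double dot = 0.0;
    for (int i = 0; i < p; ++i)
      if (i != j) {
        dot += W(i, j) * B(k, j);
        ++k;
      }
    const double tjj = 1.0 / (W(j, j) - dot);
    theta(j, j) = tjj;
    k = 0;
    for (int i = 0; i < p; ++i)
      if (i != j) theta(i, j) += -B(k++, j) * tjj;
  }
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < j; ++i) {
      const double m = 0.5 * (theta(i, j) + theta(j, i));
      theta(i, j) = m;
      theta(j, i) = m;
    }

  return List::create(_["theta"] = theta, _["W"] = W, _["B"] = B,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
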