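#include <Rcpp.h>
#include <cmath>
#include <sstream>
#include <vector>
using namespace Rcpp;

// Adams-Bashforth-Moulton predictor-corrector for the Caputo
// fractional initial-value problem D^alpha x = f(x), x(0) = x0,
// 0 < alpha <= 1, on the uniform grid t_n = n h.
//
// Predictor (fractional rectangle rule):
//   x^P_{n+1} = x0 + h^a/Gamma(a+1) * sum_{j=0}^{n}
//               [(n+1-j)^a - (n-j)^a] f_j
// Corrector (fractional trapezoidal weights):
//   x_{n+1} = x0 + h^a/Gamma(a+2) * [ f(x^P_{n+1})
//             + (n^{a+1} - (n-a)(n+1)^a) f_0
//             + sum_{j=1}^{n} ((n-j+2)^{a+1} + (n-j)^{a+1}
//                              - 2 (n-j+1)^{a+1}) f_j ]
// At alpha = 1 the weights reduce to the classical one-step
// Euler-predictor / trapezoid-corrector pair.
//
// Full memory is retained (no short-memory truncation): cost O(N^2 d).

// warm_x / warm_f: optional precomputed leading rows (state and rhs
// values at t_0..t_{s-1}) from a startup refinement; pass 0-row
// matrices to start from the initial condition alone.

// [[Rcpp::export]]
NumericMatrix abm_core(Function rhs, NumericVector x0, double alpha,
                       double h, int n_steps, int corrector_iters,
                       NumericMatrix warm_x, NumericMatrix warm_f) {
  const int d = x0.size();
  if (n_steps < 1) stop("'n_steps' must be at least 1");
  if (!(alpha > 0.0 && alpha <= 1.0)) stop("'alpha' must lie in (0, 1]");
  if (!(h > 0.0)) stop("step size 'h' must be positive");
  if (corrector_iters < 1) stop("'corrector_iters' must be at least 1");

  NumericMatrix X(n_steps + 1, d);
  NumericMatrix F(n_steps + 1, d);

  for (int c = 0; c < d; ++c) X(0, c) = x0[c];
  {
    NumericVector f0 = as<NumericVector>(rhs(x0));
    if (f0.size() != d) stop("rhs returned a vector of the wrong length");
    for (int c = 0; c < d; ++c) F(0, c) = f0[c];
  }
  int n_warm = warm_x.nrow();
  if (n_warm > 0) {
    if (warm_f.nrow() != n_warm || warm_x.ncol() != d || warm_f.ncol() != d)
      stop("warm-start matrices must agree in shape");
    if (n_warm > n_steps) n_warm = n_steps;
    for (int j = 0; j < n_warm; ++j)
      for (int c = 0; c < d; ++c) {
        X(j, c) = warm_x(j, c);
        F(j, c) = warm_f(j, c);
      }
  }

  // precomputed integer powers m^alpha and m^(alpha+1)
  std::vector<double> pa(n_steps + 2), p1(n_steps + 2);
  for (int m = 0; m <= n_steps + 1; ++m) {
    pa[m] = std::pow((double)m, alpha);
    p1[m] = std::pow((double)m, alpha + 1.0);
  }
  const double c_pred = std::pow(h, alpha) / R::gammafn(alpha + 1.0);
  const double c_corr = std::pow(h, alpha) / R::gammafn(alpha + 2.0);

  std::vector<double> sum(d), hist(d), xn(d);
  NumericVector xv(d);

  const int n_first = (n_warm > 0) ? n_warm - 1 : 0;
  for (int n = n_first; n < n_steps; ++n) {
    // predictor sum over the whole history
    for (int c = 0; c < d; ++c) sum[c] = 0.0;
    for (int j = 0; j <= n; ++j) {
      const double b = pa[n + 1 - j] - pa[n - j];
      for (int c = 0; c < d; ++c) sum[c] += b * F(j, c);
    }
    for (int c = 0; c < d; ++c) xv[c] = x0[c] + c_pred * sum[c];
    NumericVector fp = as<NumericVector>(rhs(xv));
    if (fp.size() != d) stop("rhs returned a vector of the wrong length");

    // corrector history sum (weight of f_{n+1} itself is 1)
    const double a0 = p1[n] - (n - alpha) * pa[n + 1];
    for (int c = 0; c < d; ++c) hist[c] = a0 * F(0, c);
    for (int j = 1; j <= n; ++j) {
      const double w = p1[n - j + 2] + p1[n - j] - 2.0 * p1[n - j + 1];
      for (int c = 0; c < d; ++c) hist[c] += w * F(j, c);
    }

    NumericVector fnew = fp;
    for (int it = 0; it < corrector_iters; ++it) {
      for (int c = 0; c < d; ++c)
        xv[c] = x0[c] + c_corr * (fnew[c] + hist[c]);
      fnew = as<NumericVector>(rhs(xv));
      if (fnew.size() != d) stop("rhs returned a vector of the wrong length");
    }
    for (int c = 0; c < d; ++c) xn[c] = xv[c];

    for (int c = 0; c < d; ++c) {
      if (!R_finite(xn[c])) {
        std::ostringstream msg;
        msg << "non-finite state at step " << (n + 1) << " (t = "
            << (n + 1) * h << "); last finite state at step " << n << ": (";
        for (int cc = 0; cc < d; ++cc) {
          msg << X(n, cc);
          if (cc + 1 < d) msg << ", ";
        }
        msg << ")";
        stop(msg.str());
      }
    }
    for (int c = 0; c < d; ++c) {
      X(n + 1, c) = xn[c];
      F(n + 1, c) = fnew[c];
    }
  }
  return X;
}
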