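#include <Rcpp.h>
using namespace Rcpp;

static inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Forward filter for the Bernoulli random-walk state-space model:
//   x_i = x_{i-1} + v_i, v_i ~ N(0, sigma2v);  b_i ~ Bernoulli(logistic(x_i))
// Posterior-mode update solved per step by Newton iteration.
// [[Rcpp::export]]
List bsp_filter_cpp(const IntegerVector& b, double sigma2v,
                    double x0_mean, double x0_var,
                    int newton_max = 100, double newton_tol = 1e-10) {
  const int n = b.size();
  NumericVector m(n), v(n), mp(n), vp(n);
  double prev_m = x0_mean, prev_v = x0_var;
  for (int i = 0; i < n; ++i) {
    const double pred_m = prev_m;
    const double pred_v = prev_v + sigma2v;
    mp[i] = pred_m; vp[i] = pred_v;
    // f(x) = x - pred_m - pred_v * (b - logistic(x)) is strictly
    // increasing with a root inside [pred_m + pred_v*(b-1), pred_m +
    // pred_v*b]; use Newton safeguarded by that bracket (bisection step
    // whenever Newton would leave it).
    double lo = pred_m + pred_v * ((double)b[i] - 1.0);
    double hi = pred_m + pred_v * (double)b[i];
    double x = pred_m;
    if (x < lo || x > hi) x = 0.5 * (lo + hi);
    bool ok = false;
    for (int k = 0; k < newton_max; ++k) {
      const double p = logistic(x);
      const double f = x - pred_m - pred_v * ((double)b[i] - p);
      if (f > 0.0) hi = x; else lo = x;
      if (hi - lo < newton_tol) { ok = true; break; }
      const double fp = 1.0 + pred_v * p * (1.0 - p);
      double xn = x - f / fp;
      // force a bisection step every other iteration: Newton alone can
      // ping-pong between the logistic's saturated tails when pred_v is
      // large, so guarantee the bracket halves at least every 2 steps
      if (xn <= lo || xn >= hi || (k & 1)) xn = 0.5 * (lo + hi);
      if (std::fabs(xn - x) < newton_tol) { x = xn; ok = true; break; }
      x = xn;
    }
    if (!ok)
      stop("mode search did not converge in the forward filter at step %d",
           i + 1);
    const double p = logistic(x);
    m[i] = x;
    v[i] = 1.0 / (1.0 / pred_v + p * (1.0 - p));
    prev_m = m[i];
    prev_v = v[i];
  }
  return List::create(_["mean"] = m, _["var"] = v,
                      _["pred_mean"] = mp, _["pred_var"] = vp);
}

// Fixed-interval (RTS) smoother. Returns smoothed means/variances and the
// lag-one smoothed covariances cov(x_{i+1}, x_i | all data) needed by the
// EM variance update.
// [[Rcpp::export]]
List bsp_smooth_cpp(const NumericVector& m, const NumericVector& v,
                    const NumericVector& mp, const NumericVector& vp) {
  const int n = m.size();
  NumericVector xs(n), vs(n), cov1(std::max(n - 1, 0));
  xs[n - 1] = m[n - 1];
  vs[n - 1] = v[n - 1];
  for (int i = n - 2; i >= 0; --i) {
    const double A = v[i] / vp[i + 1];
    xs[i] = m[i] + A * (xs[i + 1] - mp[i + 1]);
    vs[i] = v[i] + A * A * (vs[i + 1] - vp[i + 1]);
    cov1[i] = A * vs[i + 1];
  }
  return List::create(_["mean"] = xs, _["var"] = vs, _["cov1"] = cov1);
}
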