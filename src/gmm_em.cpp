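// EM inner loop for univariate Gaussian mixtures with component-specific
// variances. The screen fits tens of thousands of mixtures (every gene x
// every candidate k x restarts), so the per-iteration work lives in C++;
// initialization, label ordering and BIC stay in R (see R/gmm.R). A pure-R
// reference implementation of the same updates is kept in the test suite
// as an oracle.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".gmm_em_cpp")]]
List gmm_em_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector v0, double tol, int max_iter, double vfloor) {
  const int n = x.size();
  const int k = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(v0.begin(), v0.end());
  NumericMatrix resp(n, k);
  std::vector<double> trace;
  trace.reserve(128);

  const double l2pi = std::log(2.0 * M_PI);
  std::vector<double> lw(k), lg(k), nk(k), s1(k), s2(k);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  int it = 0;

  for (it = 1; it <= max_iter; ++it) {
    for (int j = 0; j < k; ++j) {
      lw[j] = std::log(w[j]) - 0.5 * l2pi - 0.5 * std::log(v[j]);
      nk[j] = s1[j] = s2[j] = 0.0;
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < k; ++j) {
        const double d = x[i] - mu[j];
        lg[j] = lw[j] - 0.5 * d * d / v[j];
        if (lg[j] > mx) mx = lg[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) {
        lg[j] = std::exp(lg[j] - mx);
        s += lg[j];
      }
      ll += mx + std::log(s);
      for (int j = 0; j < k; ++j) {
        const double r = lg[j] / s;
        resp(i, j) = r;
        nk[j] += r;
        s1[j] += r * x[i];
        s2[j] += r * x[i] * x[i];
      }
    }
    trace.push_back(ll);
    if (R_finite(ll_old) && std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + tol)) {
      converged = true;
      break;
    }
    ll_old = ll;
    for (int j = 0; j < k; ++j) {
      const double nkj = std::max(nk[j], 1e-12);
      w[j] = nkj / n;
      mu[j] = s1[j] / nkj;
      const double vv = s2[j] / nkj - mu[j] * mu[j];
      v[j] = std::max(vv, vfloor);
    }
  }
  if (it > max_iter) it = max_iter;

  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["v"] = NumericVector(v.begin(), v.end()),
    _["loglik"] = ll,
    _["resp"] = resp,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["converged"] = converged,
    _["iterations"] = it);
}
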