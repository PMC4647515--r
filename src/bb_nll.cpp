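#include <Rcpp.h>
using namespace Rcpp;

// log Beta-Binomial pmf (without the binomial coefficient) in the (mu, rho)
// parameterization alpha = mu s, beta = (1 - mu) s with s = (1 - rho) / rho,
// written as rising factorials (exact for integer k, n):
//   sum_{j<k} log(alpha + j) + sum_{j<n-k} log(beta + j) - sum_{j<n} log(s + j)
// The caller supplies ldenom = sum_{j<n} log(s + j).
// rho below 1e-8 falls through to the Binomial limit.
static inline double bb_logpmf_core(int k, int n, double mu, double rho,
                                    double s, double ldenom) {
  if (rho < 1e-8)
    return k * std::log(mu) + (n - k) * std::log1p(-mu);
  double a = mu * s, b = (1.0 - mu) * s, acc = -ldenom;
  for (int j = 0; j < k; ++j) acc += std::log(a + j);
  for (int j = 0; j < n - k; ++j) acc += std::log(b + j);
  return acc;
}

// Negative marginal log-likelihood of the Beta-Binomial mixed model.
// Per patient the product of BB terms is integrated over a Gaussian random
// intercept b ~ N(0, sigma_b^2) by Gauss-Hermite quadrature:
//   integral f(b) phi(b) db  ~=  sum_q (w_q / sqrt(pi)) f(sqrt(2) sigma x_q).
// patient must be 0-based indices into n_pat groups.
// [[Rcpp::export]]
double bb_mixed_nll_cpp(NumericVector beta, double sigma_b, double rho,
                        IntegerVector k, IntegerVector n,
                        NumericMatrix X, IntegerVector patient, int n_pat,
                        NumericVector gh_x, NumericVector gh_w) {
  int nobs = k.size(), q = gh_x.size(), p = beta.size();
  if (X.nrow() != nobs || patient.size() != nobs || X.ncol() != p)
    stop("design dimensions do not match observations");
  std::vector<double> eta(nobs), lc(nobs);
  int nmax = 0;
  for (int i = 0; i < nobs; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    lc[i] = R::lchoose((double) n[i], (double) k[i]);
    if (n[i] > nmax) nmax = n[i];
  }
  // cumulative denominator: ldenom_cum[n] = sum_{j<n} log(s + j)
  double s = (rho >= 1e-8) ? (1.0 - rho) / rho : 0.0;
  std::vector<double> ldenom_cum(nmax + 1, 0.0);
  for (int j = 0; j < nmax; ++j)
    ldenom_cum[j + 1] = ldenom_cum[j] + ((rho >= 1e-8) ? std::log(s + j) : 0.0);
  const double sqrt2 = std::sqrt(2.0), lsqrtpi = 0.5 * std::log(M_PI);
  // acc[pat * q + node] accumulates the conditional log-likelihood
  std::vector<double> acc((size_t) n_pat * q, 0.0);
  for (int i = 0; i < nobs; ++i) {
    int pa = patient[i];
    if (pa < 0 || pa >= n_pat) stop("patient index out of range");
    double ld = ldenom_cum[n[i]];
    for (int m = 0; m < q; ++m) {
      double mu = 1.0 / (1.0 + std::exp(-(eta[i] + sqrt2 * sigma_b * gh_x[m])));
      if (mu < 1e-12) mu = 1e-12;
      if (mu > 1.0 - 1e-12) mu = 1.0 - 1e-12;
      acc[(size_t) pa * q + m] += lc[i] + bb_logpmf_core(k[i], n[i], mu, rho, s, ld);
    }
  }
  double ll = 0.0;
  for (int pa = 0; pa < n_pat; ++pa) {
    double mx = R_NegInf;
    for (int m = 0; m < q; ++m) {
      double v = acc[(size_t) pa * q + m] + std::log(gh_w[m]) - lsqrtpi;
      acc[(size_t) pa * q + m] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int m = 0; m < q; ++m) s += std::exp(acc[(size_t) pa * q + m] - mx);
    double li = mx + std::log(s);
    if (!std::isfinite(li))
      stop("non-finite likelihood contribution for patient group %d", pa + 1);
    ll += li;
  }
  return -ll;
}
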