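#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Probability recursions for compound count distributions.
//
// All recursions have nonnegative terms, so they are run in linear space
// with a shared log-scale offset; whenever the newest value exceeds a
// threshold the whole history is rescaled.  This keeps q_s computable at
// total means of order 10^3-10^4 (where log q_0 is far below the double
// underflow limit) without resorting to log-space convolutions.

namespace {

const double kRescaleAt = 1e280;

void rescaleAll(std::vector<double>& q, int upto, double& logScale) {
  double mx = q[upto];
  for (int i = 0; i <= upto; ++i) q[i] /= mx;
  logScale += std::log(mx);
}

NumericVector toLog(const std::vector<double>& q, double logScale) {
  NumericVector out(q.size());
  for (std::size_t i = 0; i < q.size(); ++i)
    out[i] = (q[i] > 0.0) ? std::log(q[i]) + logScale : R_NegInf;
  return out;
}

}  // namespace

// Panjer recursion q_i = sum_{j=1..i} (a + b j/i) f_j q_{i-j} for a counting
// law in the (a, b, 0) class: negative binomial a = (dF-1)/dF,
// b = (muF-dF+1)/dF, or Poisson a = 0, b = lambda.  'f' holds the
// generalizing pmf f_0..f_K and 'logq0' the log pgf of the counting law
// evaluated at f_0.  Returns log q_0..q_kmax.
// [[Rcpp::export(name = ".panjerLogPmf")]]
NumericVector panjerLogPmf(double a, double b, double logq0,
                           NumericVector f, int kmax) {
  if (kmax < 0) stop("kmax must be >= 0");
  if (a >= 1.0) stop("Panjer recursion diverges: a >= 1");
  if (a + b <= 0.0) {
    // degenerate counting law (mass only at N = 0)
    std::vector<double> q(kmax + 1, 0.0);
    q[0] = 1.0;
    return toLog(q, logq0);
  }
  const int kf = f.size() - 1;
  const double f0 = (kf >= 0) ? f[0] : 0.0;
  // mass of the generalizing law at zero enters through the standard
  // 1/(1 - a f0) factor (absent when f0 = 0, e.g. logarithmic laws)
  const double denom = 1.0 - a * f0;
  std::vector<double> q(kmax + 1, 0.0);
  double logScale = logq0;
  q[0] = 1.0;
  for (int i = 1; i <= kmax; ++i) {
    double acc = 0.0;
    const int jmax = std::min(i, kf);
    for (int j = 1; j <= jmax; ++j) {
      const double fj = f[j];
      if (fj == 0.0) continue;
      acc += (a + b * j / static_cast<double>(i)) * fj * q[i - j];
    }
    acc /= denom;
    q[i] = (acc > 0.0) ? acc : 0.0;
    if (q[i] > kRescaleAt) rescaleAll(q, i, logScale);
  }
  return toLog(q, logScale);
}

// Compound Hermite recursion.  For counting Hermite(mu, delta) (population
// mean mu, dispersion index delta in (1, 2]; delta = 1 degenerates to a
// compound Poisson) and generalizing pmf f_0..f_K:
//   r_j  = sum_i f_i f_{j-i}
//   q_n  = (mu/n) sum_{i=0}^{n-1} (n-i) q_i [ (2-delta) f_{n-i}
//                                           + (delta-1)/2 * r_{n-i} ]
//   log q_0 = mu[ (2-delta)(f_0 - 1) + (delta-1)(f_0^2 - 1)/2 ].
// Returns log q_0..q_kmax.
// [[Rcpp::export(name = ".hermiteCompoundLogPmf")]]
NumericVector hermiteCompoundLogPmf(double mu, double delta,
                                    NumericVector f, int kmax) {
  if (kmax < 0) stop("kmax must be >= 0");
  if (delta < 1.0 || delta > 2.0)
    stop("Hermite counting dispersion must lie in [1, 2]");
  if (mu < 0.0) stop("mu must be nonnegative");
  const int kf = f.size() - 1;

  // self-convolution of the generalizing pmf, needed up to kmax
  std::vector<double> r(kmax + 1, 0.0);
  for (int j = 0; j <= kmax; ++j) {
    double acc = 0.0;
    const int lo = std::max(0, j - kf);
    const int hi = std::min(j, kf);
    for (int i = lo; i <= hi; ++i) acc += f[i] * f[j - i];
    r[j] = acc;
  }

  const double f0 = (kf >= 0) ? f[0] : 0.0;
  double logScale = mu * ((2.0 - delta) * (f0 - 1.0) +
                          (delta - 1.0) * (f0 * f0 - 1.0) / 2.0);
  std::vector<double> q(kmax + 1, 0.0);
  q[0] = 1.0;
  for (int n = 1; n <= kmax; ++n) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      const int d = n - i;
      const double fd = (d <= kf) ? f[d] : 0.0;
      const double w = (2.0 - delta) * fd + 0.5 * (delta - 1.0) * r[d];
      if (w != 0.0) acc += static_cast<double>(d) * q[i] * w;
    }
    acc *= mu / static_cast<double>(n);
    q[n] = (acc > 0.0) ? acc : 0.0;
    if (q[n] > kRescaleAt) rescaleAll(q, n, logScale);
  }
  return toLog(q, logScale);
}
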