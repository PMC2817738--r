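#include <Rcpp.h>
using namespace Rcpp;

static inline double logaddexp(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Thermodynamic occupancy with hard-core exclusion.
//
// logw[i] = mu - E(i) for footprint start i (1-based start i covers bases
// i..i+L-1); masked starts carry -Inf. All recursions are in log space, so
// the contract |E| <= 50 on chromosome-scale inputs cannot overflow.
//
// lf[b] = log partition function of bases 1..b, lb[b] = of bases b..n.
// P(start i) = exp(lf[i-1] + logw[i] + lb[i+L] - logZ); per-base occupancy
// is the windowed sum of start probabilities.
// [[Rcpp::export]]
List occupancy_dp(NumericVector logw, int L, int n) {
  int S = logw.size();
  NumericVector occ(n >= 0 ? n : 0, 0.0);
  NumericVector pstart(S > 0 ? S : 0, 0.0);
  if (S <= 0 || L > n) {
    return List::create(_["occupancy"] = occ, _["p_start"] = pstart,
                        _["log_partition"] = 0.0);
  }
  std::vector<double> lf(n + 1, 0.0), lb(n + 2, 0.0);
  for (int b = 1; b <= n; ++b) {
    double v = lf[b - 1];
    int s = b - L + 1;
    if (s >= 1) {
      double w = logw[s - 1];
      if (w != R_NegInf) v = logaddexp(v, w + lf[s - 1]);
    }
    lf[b] = v;
  }
  for (int b = n; b >= 1; --b) {
    double v = lb[b + 1];
    if (b <= S) {
      double w = logw[b - 1];
      if (w != R_NegInf) v = logaddexp(v, w + lb[b + L]);
    }
    lb[b] = v;
  }
  double logZ = lf[n];
  for (int i = 1; i <= S; ++i) {
    double w = logw[i - 1];
    if (w == R_NegInf) continue;
    pstart[i - 1] = std::exp(lf[i - 1] + w + lb[i + L] - logZ);
  }
  std::vector<double> cp(S + 1, 0.0);
  for (int i = 1; i <= S; ++i) cp[i] = cp[i - 1] + pstart[i - 1];
  for (int j = 1; j <= n; ++j) {
    int lo = j - L + 1 > 1 ? j - L + 1 : 1;
    int hi = j < S ? j : S;
    double v = (hi >= lo) ? cp[hi] - cp[lo - 1] : 0.0;
    if (v < 0.0) v = 0.0;
    if (v > 1.0) v = 1.0;
    occ[j - 1] = v;
  }
  return List::create(_["occupancy"] = occ, _["p_start"] = pstart,
                      _["log_partition"] = logZ);
}
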